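test_that("the dissimilarity is a squared kernel norm", {
  cfg <- quick_cfg()
  a <- random_fshape(seed = 1)
  b <- random_fshape(seed = 2)
  expect_equal(fvarifold_dissimilarity(a, a, cfg), 0)
  expect_equal(fvarifold_dissimilarity(a, b, cfg),
               fvarifold_dissimilarity(b, a, cfg), tolerance = 1e-12)
  expect_gte(fvarifold_dissimilarity(a, b, cfg), 0)
})

test_that("single-triangle meshes match the closed form in the signal offset", {
  tri <- function(sig) {
    v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
    fshape(tri_mesh(v, matrix(1:3, 1, 3), v[, 1:2], 1), rep(sig, 3))
  }
  cfg <- quick_cfg()
  for (delta in c(0.5, 3, 10)) {
    a <- tri(70); b <- tri(70 + delta)
    area <- 0.5
    expected <- 2 * area^2 * (1 - exp(-delta^2 / cfg$sigma_sig^2))
    expect_equal(fvarifold_dissimilarity(a, b, cfg), expected,
                 tolerance = 1e-12)
  }
})

test_that("the kernel sums equal the brute-force double-sum oracle", {
  cfg <- quick_cfg()
  for (seed in 1:4) {
    a <- random_fshape(n = 3, seed = seed)        # 8 faces
    b <- random_fshape(n = 3, seed = seed + 10)
    expect_equal(fvarifold_dissimilarity(a, b, cfg),
                 oracle_dissimilarity(a, b, cfg),
                 tolerance = 1e-10)
    # and on asymmetric sizes
    c4 <- random_fshape(n = 4, seed = seed + 20)  # 18 faces
    expect_equal(fvarifold_dissimilarity(a, c4, cfg),
                 oracle_dissimilarity(a, c4, cfg),
                 tolerance = 1e-10)
  }
})

test_that("zero-area faces are skipped with a warning", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0))
  faces <- rbind(c(1, 2, 3), c(1, 2, 4))  # second face is collinear
  fs <- fshape(tri_mesh(v, faces, v[, 1:2], 1), rep(70, 4))
  good <- fshape(tri_mesh(v[1:3, ], matrix(1:3, 1, 3), v[1:3, 1:2], 1),
                 rep(70, 3))
  cfg <- quick_cfg()
  expect_warning(val <- fvarifold_dissimilarity(fs, good, cfg), "zero-area")
  expect_equal(val, 0)  # surviving face is identical to `good`
})

test_that("varifold gradients match central finite differences", {
  cfg <- quick_cfg()
  a <- random_fshape(n = 4, seed = 3)
  b <- random_fshape(n = 4, seed = 4)
  gr <- macfshape:::fvarifold_grad(a, b, cfg)
  eps <- 1e-6
  set.seed(5)
  for (k in 1:6) {
    i <- sample(nrow(a$mesh$vertices), 1); d <- sample(3, 1)
    ap <- a; ap$mesh$vertices[i, d] <- ap$mesh$vertices[i, d] + eps
    am <- a; am$mesh$vertices[i, d] <- am$mesh$vertices[i, d] - eps
    num <- (fvarifold_dissimilarity(ap, b, cfg) -
              fvarifold_dissimilarity(am, b, cfg)) / (2 * eps)
    expect_equal(gr$gV[i, d], num, tolerance = 1e-5)
    sp <- a; sp$signal[i] <- sp$signal[i] + eps
    sm <- a; sm$signal[i] <- sm$signal[i] - eps
    nums <- (fvarifold_dissimilarity(sp, b, cfg) -
               fvarifold_dissimilarity(sm, b, cfg)) / (2 * eps)
    expect_equal(gr$gs[i], nums, tolerance = 1e-5)
  }
})
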