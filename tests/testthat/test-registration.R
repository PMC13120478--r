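test_that("the objective decomposes term by term", {
  cfg <- quick_cfg()
  tmpl <- grid_fshape(4, signal = function(x, y) 0 * x)
  n <- nrow(tmpl$mesh$vertices)
  zero <- registration_params(matrix(0, n, 3), numeric(n))

  # zero template signal, zero params, subjects identical to template -> 0
  J0 <- evaluate_objective(tmpl, list(tmpl, tmpl), list(zero, zero), cfg)
  expect_equal(J0$value, 0, tolerance = 1e-10)

  # all params zero: J = gamma_f ||f_m||^2_w + sum_i gamma_w A(template, s_i)
  tmpl2 <- grid_fshape(4)
  subj <- random_fshape(n = 4, seed = 8)
  J <- evaluate_objective(tmpl2, list(subj), list(zero), cfg)
  w <- macfshape:::vertex_area_weights(tmpl2$mesh)
  expect_equal(J$value,
               cfg$gamma_f * sum(tmpl2$signal^2 * w) +
                 cfg$gamma_w * fvarifold_dissimilarity(tmpl2, subj, cfg),
               tolerance = 1e-8)

  # scaling gamma_w rescales only the attachment term
  cfg2 <- quick_cfg(gamma_w = 7)
  J2 <- evaluate_objective(tmpl2, list(subj), list(zero), cfg2)
  expect_equal(J2$value - J$value,
               6 * cfg$gamma_w * sum(J$terms$attachment), tolerance = 1e-8)

  expect_error(evaluate_objective(tmpl2, list(subj), list(), cfg), "align")
})

test_that("objective gradients match finite differences through all blocks", {
  cfg <- quick_cfg(shoot_steps = 4L)
  tmpl <- grid_fshape(4)
  subj <- random_fshape(n = 4, seed = 9)
  w <- macfshape:::vertex_area_weights(tmpl$mesh)
  K0 <- gaussian_gram(tmpl$mesh$vertices, cfg$sigma_V)
  sg <- macfshape:::subject_geometry(subj, cfg)
  set.seed(10)
  prm <- registration_params(matrix(rnorm(48, sd = 0.05), 16, 3),
                             rnorm(16))
  st <- macfshape:::subject_term(tmpl, sg, prm, cfg, w, K0, grad = TRUE)
  f <- function(p, z) {
    macfshape:::subject_term(tmpl, sg, registration_params(p, z),
                             cfg, w, K0)$value
  }
  eps <- 1e-6
  for (i in c(1L, 7L, 16L)) {
    for (d in 1:3) {
      pp <- prm$p; pp[i, d] <- pp[i, d] + eps
      pm <- prm$p; pm[i, d] <- pm[i, d] - eps
      expect_equal(st$grad_p[i, d],
                   (f(pp, prm$zeta) - f(pm, prm$zeta)) / (2 * eps),
                   tolerance = 1e-5)
    }
    zp <- prm$zeta; zp[i] <- zp[i] + eps
    zm <- prm$zeta; zm[i] <- zm[i] - eps
    expect_equal(st$grad_zeta[i],
                 (f(prm$p, zp) - f(prm$p, zm)) / (2 * eps),
                 tolerance = 1e-5)
  }
  # cached-state evaluators agree exactly with the reference path
  stc <- macfshape:::subject_state(tmpl, sg, prm, cfg, w, K0)
  expect_equal(stc$value, st$value, tolerance = 1e-12)
})

test_that("registering an F-shape onto itself is a fixed point", {
  cfg <- quick_cfg(max_iter = 30L)
  fs <- grid_fshape(6)
  r <- register_subject(fs, fs, cfg)
  expect_lt(abs(r$trace[1] - r$trace[length(r$trace)]), 1e-8)
  expect_lt(max(abs(r$params$zeta)), 1e-6)
  expect_lt(max(abs(r$params$p)), 1e-6)
  expect_lt(sqrt(mean((fs$signal - r$registered$signal)^2)), 1e-6)
})

test_that("a constant signal offset is absorbed by the increments", {
  cfg <- quick_cfg(gamma_zeta = 1e-4, sigma_sig = 50, max_iter = 120L,
                   tol = 1e-10)
  tmpl <- grid_fshape(6)
  subj <- fshape(tmpl$mesh, tmpl$signal + 5)
  r <- register_subject(tmpl, subj, cfg)
  expect_equal(mean(r$params$zeta), 5, tolerance = 0.25)
})

test_that("accepted traces never increase", {
  for (seed in 1:4) {
    cfg <- quick_cfg(max_iter = 15L)
    tmpl <- random_fshape(n = 5, seed = seed)
    subj <- random_fshape(n = 5, seed = seed + 50)
    r <- register_subject(tmpl, subj, cfg)
    expect_true(all(diff(r$trace) <= 1e-12))
  }
})
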