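test_that("Gaussian Gram matrices behave like a PSD kernel", {
  expect_equal(gaussian_gram(rbind(c(0, 0, 0), c(0, 0, 0)), 1),
               matrix(1, 2, 2))
  far <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_lt(gaussian_gram(far, 1)[1, 2], 1e-12)
  set.seed(7)
  for (k in 1:5) {
    pts <- matrix(rnorm(15), 5, 3)
    K <- gaussian_gram(pts, runif(1, 0.3, 2))
    expect_equal(K, t(K))
    expect_true(all(diag(K) == 1))
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
  expect_error(gaussian_gram(matrix(0, 2, 3), 0), "positive")
})

test_that("geodesic shooting is the identity at zero momenta and exact for one point", {
  fs <- grid_fshape(5)
  cfg <- quick_cfg()
  m0 <- deform(fs$mesh, matrix(0, 25, 3), cfg)
  expect_identical(m0$vertices, fs$mesh$vertices)

  # single free particle: K = 1, one Euler step translates by p exactly
  cfg1 <- registration_config(sigma_V = 1, shoot_steps = 1L)
  out <- shoot_forward(matrix(0, 1, 3), matrix(c(1, 0, 0), 1, 3), cfg1)
  expect_equal(out$x, matrix(c(1, 0, 0), 1, 3))

  # kernel-constant limit: uniform momenta translate rigidly
  cfgw <- registration_config(sigma_V = 1e4, shoot_steps = 8L)
  p <- matrix(rep(c(0.02, -0.01, 0.03), each = 25), 25, 3)
  def <- deform(fs$mesh, p, cfgw)
  disp <- def$vertices - fs$mesh$vertices
  expect_lt(max(abs(sweep(disp, 2, colMeans(disp)))), 1e-6)
})

test_that("geodesic energy is the quadratic form p'Kp", {
  fs <- grid_fshape(4)
  cfg <- quick_cfg()
  expect_equal(geodesic_energy(fs$mesh, matrix(0, 16, 3), cfg), 0)
  one <- tri_mesh(matrix(0, 1, 3), matrix(1, 0, 3), matrix(0L, 1, 2), 1)
  expect_equal(geodesic_energy(one, matrix(c(2, 0, 0), 1, 3), cfg), 4)
  set.seed(2)
  p <- matrix(rnorm(48, sd = 0.1), 16, 3)
  expect_equal(geodesic_energy(fs$mesh, 2 * p, cfg),
               4 * geodesic_energy(fs$mesh, p, cfg))
})

test_that("the shooting adjoint matches central finite differences", {
  set.seed(11)
  x0 <- matrix(rnorm(27), 9, 3)
  p0 <- matrix(rnorm(27, sd = 0.3), 9, 3)
  wts <- matrix(rnorm(27), 9, 3)
  cfg <- registration_config(sigma_V = 0.9, shoot_steps = 4L)
  sh <- shoot_forward(x0, p0, cfg, keep_trajectory = TRUE)
  pb <- macfshape:::shoot_pullback(sh$traj, wts, cfg)
  eps <- 1e-6
  for (idx in list(c(1, 1), c(5, 2), c(9, 3))) {
    i <- idx[1]; d <- idx[2]
    pp <- p0; pp[i, d] <- pp[i, d] + eps
    pm <- p0; pm[i, d] <- pm[i, d] - eps
    num <- (sum(wts * shoot_forward(x0, pp, cfg)$x) -
              sum(wts * shoot_forward(x0, pm, cfg)$x)) / (2 * eps)
    expect_equal(pb$gp[i, d], num, tolerance = 1e-6)
    xp <- x0; xp[i, d] <- xp[i, d] + eps
    xm <- x0; xm[i, d] <- xm[i, d] - eps
    numx <- (sum(wts * shoot_forward(xp, p0, cfg)$x) -
               sum(wts * shoot_forward(xm, p0, cfg)$x)) / (2 * eps)
    expect_equal(pb$gx[i, d], numx, tolerance = 1e-6)
  }
})

test_that("diverging momenta raise a numerical error", {
  fs <- grid_fshape(4, span = 1)
  cfg <- registration_config(sigma_V = 0.5, shoot_steps = 3L)
  huge <- matrix(1e200, 16, 3)
  expect_error(shoot_forward(fs$mesh$vertices, huge, cfg), "diverged")
})
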