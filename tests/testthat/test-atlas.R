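test_that("identical subjects collapse to equal registrations and zero residuals", {
  cfg <- quick_cfg(max_iter = 20L, update_geometry = FALSE)
  s <- grid_fshape(5)
  hyper <- fshape(s$mesh, numeric(25))
  at <- estimate_atlas(list(s, s, s), hyper, cfg, max_outer = 12L)
  expect_true(all(diff(at$objective_trace) <= 1e-9))
  res <- compute_residuals(at)
  expect_equal(res$matrix[1, ], res$matrix[2, ], tolerance = 1e-10)
  expect_equal(res$matrix[2, ], res$matrix[3, ], tolerance = 1e-10)
  # residuals shrink as the template signal approaches the common subject
  expect_lt(sqrt(mean(res$matrix^2)), sqrt(mean(s$signal^2)))
})

test_that("with a weak template prior the template signal tracks the subjects", {
  cfg <- quick_cfg(gamma_f = 1e-8, gamma_w = 10, gamma_zeta = 10,
                   sigma_sig = 60, max_iter = 25L, update_geometry = FALSE)
  s <- grid_fshape(5)
  hyper <- fshape(s$mesh, numeric(25))
  rms_to_subject <- function(outer) {
    at <- estimate_atlas(list(s, s), hyper, cfg, max_outer = outer)
    sqrt(mean((at$template$signal - s$signal)^2))
  }
  rms0 <- sqrt(mean(s$signal^2))                  # template starts at zero
  rms <- vapply(c(5L, 15L, 40L), rms_to_subject, numeric(1))
  # RMS distance to the common subject field decreases across iterations
  # and ends well below the starting distance
  expect_true(all(diff(rms) < 0))
  expect_lt(rms[3], 0.35 * rms0)
})

test_that("atlas estimation is deterministic and residuals match subtraction", {
  cfg <- quick_cfg(max_iter = 10L, update_geometry = FALSE)
  subs <- list(random_fshape(n = 4, seed = 1), random_fshape(n = 4, seed = 2))
  hyper <- fshape(subs[[1]]$mesh, numeric(16))
  a1 <- estimate_atlas(subs, hyper, cfg, max_outer = 5L)
  a2 <- estimate_atlas(subs, hyper, cfg, max_outer = 5L)
  expect_identical(a1$objective_trace, a2$objective_trace)
  expect_identical(a1$template$signal, a2$template$signal)

  res <- compute_residuals(a1, labels = c("healthy", "MS"))
  for (i in 1:2) {
    expect_equal(res$matrix[i, ],
                 a1$template$signal - a1$registered[[i]]$signal)
  }
  expect_equal(res$labels, c("healthy", "MS"))

  # connectivity mismatch is refused
  bad <- a1
  bad$registered[[1]] <- random_fshape(n = 3, seed = 3)
  expect_error(compute_residuals(bad), "connectivity")
})

test_that("template geometry updates also descend", {
  cfg <- quick_cfg(max_iter = 10L, update_geometry = TRUE)
  subs <- list(random_fshape(n = 4, seed = 4), random_fshape(n = 4, seed = 5))
  hyper <- fshape(subs[[1]]$mesh, numeric(16))
  at <- estimate_atlas(subs, hyper, cfg, max_outer = 6L)
  expect_true(all(diff(at$objective_trace) <= 1e-9))
})

test_that("tidy and glance summarize an atlas fit", {
  cfg <- quick_cfg(max_iter = 5L, update_geometry = FALSE)
  subs <- list(random_fshape(n = 4, seed = 6), random_fshape(n = 4, seed = 7))
  at <- estimate_atlas(subs, fshape(subs[[1]]$mesh, numeric(16)), cfg,
                       max_outer = 3L)
  td <- tidy(at)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$objective, at$objective_trace)
  gl <- glance(at)
  expect_equal(gl$n_subjects, 2L)
  expect_equal(gl$objective_final, at$objective_trace[length(at$objective_trace)])
  expect_s3_class(autoplot(at), "ggplot")
})
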