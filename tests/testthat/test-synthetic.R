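test_that("the healthy template has a foveal pit and the requested mean", {
  g <- healthy_profile(c(121, 121), 6 / 121, target_mean = 75.9)
  expect_equal(mean(g$values), 75.9, tolerance = 1e-6)
  center <- grid_value_at(g, 60, 60)
  ring <- grid_value_at(g, 60 + round(1 / (6 / 121)), 60)  # ~1 mm nasal
  expect_lt(center, ring)
  expect_gte(min(g$values), 0)
  expect_gt(max(g$values) / min(g$values), 10)
  # deterministic
  expect_identical(g$values, healthy_profile(c(121, 121), 6 / 121, 75.9)$values)
})

test_that("the MS effect is calibrated, confined, and horseshoe-shaped", {
  cohort <- cohort_config(grid_shape = c(121, 121), seed = 1)
  healthy <- healthy_profile(c(121, 121), cohort$pixel_pitch,
                             cohort$healthy_mean, cohort$fovea_center)
  ms <- apply_ms_effect(healthy, cohort)
  expect_equal(mean(ms$values), cohort$ms_mean, tolerance = 0.1)
  # pixels in the angular gap (temporal side, default 180 deg) unchanged
  cx <- cohort$fovea_center[1]; cy <- cohort$fovea_center[2]
  gap_x <- cx - round(1.5 / cohort$pixel_pitch)  # 1.5 mm toward 180 deg
  expect_equal(grid_value_at(ms, gap_x, cy), grid_value_at(healthy, gap_x, cy))
  # inside the horseshoe (nasal side) thinner; outside the annulus unchanged
  in_x <- cx + round(1.5 / cohort$pixel_pitch)
  expect_lt(grid_value_at(ms, in_x, cy), grid_value_at(healthy, in_x, cy))
  far_x <- cx + round(2.9 / cohort$pixel_pitch)
  expect_equal(grid_value_at(ms, far_x, cy), grid_value_at(healthy, far_x, cy))
  # infeasible thinning is refused
  bad <- cohort_config(grid_shape = c(121, 121), ms_mean = 1)
  expect_error(apply_ms_effect(healthy, bad), "infeasible")
})

test_that("with no jitter or noise the difference map is zero outside the horseshoe", {
  cohort <- cohort_config(grid_shape = c(81, 81), healthy_sd = 0, ms_sd = 0,
                          anatomy_jitter = 0, noise_sd = 0, seed = 2)
  set.seed(2)
  h <- sample_subject(cohort, "healthy")
  m <- sample_subject(cohort, "MS")
  w <- macfshape:::horseshoe_weight(cohort)
  diffmap <- h$thickness$values - m$thickness$values
  expect_true(all(diffmap[w == 0] == 0))
  expect_true(all(diffmap[w > 0.5] > 0))
  # degenerate config: subject map is an exact multiple of the template
  templ <- healthy_profile(cohort$grid_shape, cohort$pixel_pitch,
                           cohort$healthy_mean, cohort$fovea_center)
  ratio <- h$thickness$values / templ$values
  expect_lt(diff(range(ratio)), 1e-10)
})

test_that("subject draws have the configured mean structure and reproducibility", {
  cohort <- cohort_config(grid_shape = c(61, 61), seed = 3)
  set.seed(3)
  means <- replicate(200, mean(sample_subject(cohort, "healthy")$thickness$values))
  se <- cohort$healthy_sd / sqrt(200)
  expect_lt(abs(mean(means) - cohort$healthy_mean), 3 * se + 0.3)

  c1 <- simulate_cohort(cohort_config(n_healthy_eyes = 3L, n_ms_eyes = 2L,
                                      grid_shape = c(61, 61), seed = 11))
  c2 <- simulate_cohort(cohort_config(n_healthy_eyes = 3L, n_ms_eyes = 2L,
                                      grid_shape = c(61, 61), seed = 11))
  expect_identical(c1[[4]]$thickness$values, c2[[4]]$thickness$values)
  # sides alternate and ground truth is attached
  expect_equal(purrr::map_chr(c1, ~.x$thickness$eye_side)[1:4],
               c("right", "left", "right", "left"))
  expect_true(!is.null(attr(c1[[1]], "ground_truth")))
})

test_that("cohorts separate the groups at the configured effect size", {
  cohort <- cohort_config(grid_shape = c(61, 61), seed = 4)  # default 37/35 eyes
  recs <- simulate_cohort(cohort)
  mm <- purrr::map_dbl(recs, ~mean(.x$thickness$values))
  labels <- purrr::map_chr(recs, "label")
  p <- stats::t.test(mm[labels == "healthy"], mm[labels == "MS"])$p.value
  expect_lt(p, 1e-6)
})

test_that("splits are seeded, sized, and guarded", {
  labels <- c(rep("healthy", 37), rep("MS", 35))
  sp <- make_split(labels, 28, 26, seed = 5)
  expect_length(sp$train, 54)
  expect_length(sp$test, 18)
  expect_equal(sum(labels[sp$test] == "MS"), 9)
  expect_equal(sum(labels[sp$test] == "healthy"), 9)
  expect_identical(make_split(labels, 28, 26, seed = 5), sp)
  expect_error(make_split(labels, 28, 36, seed = 5), "oversubscribes")
})
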