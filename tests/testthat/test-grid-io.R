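test_that("grids round-trip through both file formats", {
  g <- thickness_grid(matrix(75.9, 3, 3))
  expect_equal(mean(g$values), 75.9)

  set.seed(1)
  g10 <- thickness_grid(matrix(runif(100, 10, 90), 10, 10),
                        pixel_pitch = 0.013)
  txt <- withr::local_tempfile(fileext = ".csv")
  write_grid(g10, txt, "delimited_text")
  back <- read_grid(txt, "delimited_text")
  expect_equal(back$values, g10$values, tolerance = 1e-12)

  bin <- withr::local_tempfile(fileext = ".bin")
  write_grid(g10, bin, "binary_container")
  back2 <- read_grid(bin, "binary_container")
  expect_identical(back2$values, g10$values)  # bit-exact
  expect_identical(back2$pixel_pitch, g10$pixel_pitch)
})

test_that("malformed grid files are rejected with located errors", {
  ragged <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,3,4,5", "1,2,3,4,5", "1,2,3,4"), ragged)
  expect_error(read_grid(ragged, "delimited_text"), "ragged")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,3", "1,zz,3"), bad)
  expect_error(read_grid(bad, "delimited_text"), "row 2, column 2")

  expect_error(read_grid("does-not-exist.csv"), "no such file")
  expect_error(thickness_grid(matrix(c(1, -2, 3, 4), 2, 2)), ">= 0")
  expect_error(thickness_grid(matrix(c(1, NA, 3, 4), 2, 2)), "finite")
})

test_that("orientation normalization mirrors left eyes and only left eyes", {
  right <- tiny_record(side = "right")
  expect_identical(normalize_orientation(right)$thickness$values,
                   right$thickness$values)

  left <- tiny_record(side = "left",
                      thick_fun = function(x, y) 50 + 3 * x)
  once <- normalize_orientation(left)
  expect_equal(once$thickness$eye_side, "right")
  # involution: flipping the flipped values restores the original
  refl <- once$thickness$values[, rev(seq_len(once$thickness$width))]
  expect_identical(refl, left$thickness$values)

  # single nonzero pixel at (x=0, y=0) on width 10 moves to (x=9, y=0)
  v <- matrix(0, 5, 10); v[1, 1] <- 7
  tg <- thickness_grid(v, eye_side = "left")
  ig <- thickness_grid(v, eye_side = "left", layer_tag = "ILM_elevation")
  rec <- normalize_orientation(subject_record("s", "e", "healthy", tg, ig))
  expect_equal(grid_value_at(rec$thickness, 9, 0), 7)
  expect_equal(sum(rec$thickness$values != 0), 1)
})

test_that("manifests round-trip and drive cohort loading", {
  dir <- withr::local_tempdir()
  cfg <- desk_study_config(seed = 3, width = 60L)
  cfg$cohort <- cohort_config(n_healthy_eyes = 2L, n_ms_eyes = 1L,
                              grid_shape = c(60L, 60L), seed = 3)
  man_path <- pipeline_simulate(cfg, dir)
  man <- read_manifest(man_path)
  expect_equal(nrow(man), 3L)
  recs <- load_cohort(man_path)
  expect_length(recs, 3L)
  expect_s3_class(recs[[1]]$thickness, "thickness_grid")
  expect_setequal(purrr::map_chr(recs, "label"), c("healthy", "MS"))
})
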