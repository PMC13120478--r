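test_that("pixels land in the expected sectors", {
  # pitch 0.02 mm, centered: radius 0.2 mm -> CF; 1 mm straight up -> IS
  eg <- build_etdrs_grid(c(301, 301), 0.02, center = c(150, 150))
  px <- function(x, y) eg$labels[y + 1, x + 1]
  expect_equal(px(150, 150), "CF")
  expect_equal(px(150 + 10, 150), "CF")   # 0.2 mm
  expect_equal(px(150 + 20, 150), "CF")   # 0.4 mm
  expect_equal(px(150, 150 + 50), "IS")   # 1.0 mm straight up (+y superior)
  expect_equal(px(150 + 50, 150), "IN")   # 1.0 mm nasal (+x, right eye)
  expect_equal(px(150, 150 - 50), "II")
  expect_equal(px(150 - 50, 150), "IT")
  expect_equal(px(150, 150 + 100), "OS")  # 2.0 mm
  expect_true(is.na(px(300, 300)))        # corner, ~4.2 mm: outside the disc
})

test_that("masks partition the disc and areas match the analytic sectors", {
  eg <- build_etdrs_grid(c(301, 301), 0.02, center = c(150, 150))
  masks <- eg$sector_masks
  total <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  expect_true(all(total <= 1L))                        # pairwise disjoint
  expect_equal(sum(total), sum(!is.na(eg$labels)))     # union = disc

  pitch2 <- 0.02^2
  analytic <- c(
    CF = pi * 0.5^2,
    setNames(rep(pi * (1.5^2 - 0.5^2) / 4, 4), c("IS", "IN", "II", "IT")),
    setNames(rep(pi * (3^2 - 1.5^2) / 4, 4), c("OS", "ON", "OI", "OT"))
  )
  for (s in names(masks)) {
    pix_area <- sum(masks[[s]]) * pitch2
    expect_lt(abs(pix_area - analytic[[s]]) / analytic[[s]], 0.02)
  }
})

test_that("sector means conserve the disc total and order monotone fields", {
  eg <- build_etdrs_grid(c(301, 301), 0.02, center = c(150, 150))
  const <- thickness_grid(matrix(75.9, 301, 301), pixel_pitch = 0.02)
  expect_true(all(abs(sector_means(const, eg) - 75.9) < 1e-12))

  # radius field: CF mean < inner ring means < outer ring means
  x <- matrix(rep(0:300, each = 301), 301, 301) - 150
  y <- matrix(rep(0:300, times = 301), 301, 301) - 150
  rmap <- thickness_grid(sqrt(x^2 + y^2) * 0.02, pixel_pitch = 0.02)
  sm <- sector_means(rmap, eg)
  expect_lt(sm["CF"], min(sm[c("IS", "IN", "II", "IT")]))
  expect_lt(max(sm[c("IS", "IN", "II", "IT")]),
            min(sm[c("OS", "ON", "OI", "OT")]))

  # checkerboard averages to ~50 in every sector
  cb <- thickness_grid(100 * ((x + y) %% 2 == 0), pixel_pitch = 0.02)
  expect_true(all(abs(sector_means(cb, eg) - 50) < 1))

  # weighted-mean conservation is exact
  counts <- vapply(eg$sector_masks, sum, numeric(1))
  disc <- !is.na(eg$labels)
  expect_equal(sum(counts * sector_means(rmap, eg)),
               sum(rmap$values[disc]), tolerance = 1e-10)
})

test_that("the grid is equivariant to the horizontal mirror", {
  eg <- build_etdrs_grid(c(101, 101), 0.06, center = c(50, 50))
  set.seed(3)
  v <- matrix(runif(101 * 101, 40, 90), 101, 101)
  tg <- thickness_grid(v, pixel_pitch = 0.06)
  sm <- sector_means(tg, eg)
  mirrored <- thickness_grid(v[, rev(seq_len(101))], pixel_pitch = 0.06)
  smm <- sector_means(mirrored, eg)
  swap <- c(CF = "CF", IS = "IS", IN = "IT", II = "II", IT = "IN",
            OS = "OS", ON = "OT", OI = "OI", OT = "ON")
  expect_equal(unname(smm[swap[names(sm)]]), unname(sm), tolerance = 1e-10)
})

test_that("degenerate grids warn or error as appropriate", {
  expect_error(build_etdrs_grid(c(50, 50), 0.1, center = c(60, 10)),
               "outside")
  expect_warning(build_etdrs_grid(c(40, 40), 0.1, center = c(20, 20)),
                 "clipped")
})
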