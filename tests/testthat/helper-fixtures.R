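# In-code fixtures: regular heightfield F-shapes and tiny subject records.

# n x n vertex grid over [0, span]^2 with a smooth height and signal field
grid_fshape <- function(n = 6, span = 3,
                        height = function(x, y) 0.1 * cos(2 * x) * sin(y),
                        signal = function(x, y) 70 + 5 * sin(x)) {
  xs <- seq(0, span, length.out = n)
  g <- expand.grid(x = xs, y = xs)
  v <- cbind(g$x, g$y, height(g$x, g$y))
  id <- function(i, j) (j - 1) * n + i
  faces <- matrix(0L, 2 * (n - 1)^2, 3)
  k <- 1L
  for (i in 1:(n - 1)) for (j in 1:(n - 1)) {
    faces[k, ] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1)); k <- k + 1L
    faces[k, ] <- c(id(i, j), id(i + 1, j + 1), id(i, j + 1)); k <- k + 1L
  }
  fshape(tri_mesh(v, faces, cbind(round(g$x), round(g$y)), 1),
         signal(g$x, g$y))
}

# random small fshape (jittered heights and signals, fixed connectivity)
random_fshape <- function(n = 5, span = 2, seed = 1) {
  set.seed(seed)
  grid_fshape(n, span,
              height = function(x, y) 0.15 * sin(3 * x) + 0.05 * rnorm(length(x)),
              signal = function(x, y) 70 + 4 * rnorm(length(x)))
}

# quick registration config for small meshes (overrides win)
quick_cfg <- function(...) {
  args <- utils::modifyList(
    list(sigma_V = 1.2, sigma_W = 0.8, sigma_sig = 30,
         shoot_steps = 5L, max_iter = 40L, tol = 1e-8),
    list(...))
  do.call(registration_config, args)
}

# tiny subject record on an m x m lattice
tiny_record <- function(m = 12, label = "healthy", side = "right",
                        thick_fun = function(x, y) 60 + x + y,
                        ilm_fun = function(x, y) 100 + 2 * x) {
  xs <- 0:(m - 1)
  thick <- outer(xs, xs, function(y, x) thick_fun(x, y))
  ilm <- outer(xs, xs, function(y, x) ilm_fun(x, y))
  tg <- thickness_grid(thick, pixel_pitch = 0.1, eye_side = side)
  ig <- thickness_grid(ilm, pixel_pitch = 0.1, eye_side = side,
                       layer_tag = "ILM_elevation")
  subject_record("S1", paste0("S1_", side), label, tg, ig)
}

# R brute-force double-sum oracle for the functional-varifold inner
# product and dissimilarity (independent of the package's kernels)
oracle_inner <- function(a, b, cfg) {
  geom <- function(fs) {
    V <- fs$mesh$vertices; F <- fs$mesh$faces
    lapply(seq_len(nrow(F)), function(k) {
      v1 <- V[F[k, 1], ]; v2 <- V[F[k, 2], ]; v3 <- V[F[k, 3], ]
      e1 <- v2 - v1; e2 <- v3 - v1
      n <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
      list(c = (v1 + v2 + v3) / 3, n = n, nl = sqrt(sum(n^2)),
           area = sqrt(sum(n^2)) / 2,
           fb = mean(fs$signal[F[k, ]]))
    })
  }
  fa <- geom(a); fb <- geom(b)
  total <- 0
  for (i in seq_along(fa)) for (j in seq_along(fb)) {
    gi <- fa[[i]]; gj <- fb[[j]]
    if (gi$nl == 0 || gj$nl == 0) next
    pos <- exp(-sum((gi$c - gj$c)^2) / cfg$sigma_W^2)
    cosn <- (sum(gi$n * gj$n) / (gi$nl * gj$nl))^2
    sig <- exp(-(gi$fb - gj$fb)^2 / cfg$sigma_sig^2)
    total <- total + pos * cosn * sig * gi$area * gj$area
  }
  total
}

oracle_dissimilarity <- function(a, b, cfg) {
  oracle_inner(a, a, cfg) - 2 * oracle_inner(a, b, cfg) +
    oracle_inner(b, b, cfg)
}
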