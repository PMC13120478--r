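#' Gaussian Gram matrix
#'
#' Entry (i, j) is `exp(-||x_i - x_j||^2 / sigma^2)`: symmetric, positive
#' semi-definite, unit diagonal. This kernel parameterizes both the
#' deformation velocity field and the varifold position/signal factors.
#'
#' @param points Numeric n x d matrix of points (rows).
#' @param sigma Kernel width, same unit as the coordinates; must be > 0.
#' @return n x n numeric matrix.
#' @export
gaussian_gram <- function(points, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a single positive number", call. = FALSE)
  }
  points <- as.matrix(points)
  d2 <- sq_dist(points, points)
  diag(d2) <- 0   # guard floating-point dust on self-distances
  exp(-d2 / sigma^2)
}

# squared Euclidean distances between rows of a (n x d) and b (m x d)
sq_dist <- function(a, b) {
  an <- rowSums(a * a); bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# rowwise cross product of n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
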