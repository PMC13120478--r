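#' Principal component analysis of a feature matrix
#'
#' Eigen-decomposition of the covariance of the mean-centered rows, via the
#' singular value decomposition. The number of retained components `k` is
#' the smallest k whose marginal gain in cumulative eigenvalue ratio falls
#' below `gain_threshold` (a reproducible proxy for the point where the
#' scree curve flattens out), unless a fixed `k` is supplied.
#'
#' @param matrix N x M numeric feature matrix (N >= 2 rows = samples).
#' @param k Fixed number of components; `NULL` to choose from the scree
#'   curve.
#' @param gain_threshold Marginal cumulative-ratio gain below which the
#'   scree curve is considered flat (default 0.01).
#' @param center Mean-center the rows before decomposition (default TRUE).
#' @return An object of class `pca_model`: `eigenvalues` (non-increasing),
#'   `components` (k x M matrix, rows = principal directions), `k`,
#'   `mean_row`, `cumulative_ratio`.
#' @export
fit_pca <- function(matrix, k = NULL, gain_threshold = 0.01, center = TRUE) {
  matrix <- as.matrix(matrix)
  N <- nrow(matrix)
  if (N < 2L) stop("PCA needs at least 2 rows", call. = FALSE)
  mean_row <- if (center) colMeans(matrix) else rep(0, ncol(matrix))
  X <- sweep(matrix, 2L, mean_row)
  sv <- svd(X, nu = 0)
  m <- min(N - 1L, ncol(matrix))
  eig <- (sv$d^2 / (N - 1L))[seq_len(m)]
  V <- t(sv$v[, seq_len(m), drop = FALSE])
  tot <- sum(eig)
  cum <- if (tot > 0) cumsum(eig) / tot else rep(1, m)
  if (is.null(k)) {
    gains <- diff(c(0, cum))
    flat <- which(gains < gain_threshold)
    k <- if (length(flat)) max(1L, flat[1L] - 1L) else m
  }
  k <- min(as.integer(k), m)
  structure(
    list(eigenvalues = eig, components = V[seq_len(k), , drop = FALSE],
         k = k, mean_row = mean_row, cumulative_ratio = cum,
         all_components = V),
    class = "pca_model"
  )
}

#' Cumulative eigenvalue-ratio (scree) curve
#'
#' @param model A `pca_model`.
#' @return Tibble with `k` and `cumulative_ratio` (non-decreasing, ending
#'   at 1).
#' @export
scree_curve <- function(model) {
  tibble::tibble(k = seq_along(model$cumulative_ratio),
                 cumulative_ratio = model$cumulative_ratio)
}

#' Project rows onto the retained principal components
#'
#' Computes `(rows - mean_row) %*% t(V_k)`.
#'
#' @param model A `pca_model`.
#' @param rows Matrix (or vector) of rows in the original feature space.
#' @param k Number of components (defaults to the model's `k`).
#' @return N x k matrix of scores.
#' @export
pca_transform <- function(model, rows, k = model$k) {
  rows <- if (is.null(dim(rows))) matrix(rows, nrow = 1L) else as.matrix(rows)
  V <- model$all_components[seq_len(k), , drop = FALSE]
  sweep(rows, 2L, model$mean_row) %*% t(V)
}

#' Reconstruct rows from principal-component scores
#'
#' @param model A `pca_model`.
#' @param scores N x k score matrix.
#' @return N x M matrix in the original feature space.
#' @export
pca_inverse <- function(model, scores) {
  scores <- as.matrix(scores)
  V <- model$all_components[seq_len(ncol(scores)), , drop = FALSE]
  sweep(scores %*% V, 2L, model$mean_row, "+")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d eigenvalues, k = %d (cumulative ratio %.3f)\n",
              length(x$eigenvalues), x$k, x$cumulative_ratio[x$k]))
  invisible(x)
}

#' Scree plot
#' @param object A `pca_model`.
#' @param ... Unused.
#' @return A ggplot of the cumulative eigenvalue-ratio curve.
#' @method autoplot pca_model
#' @export
autoplot.pca_model <- function(object, ...) {
  ggplot2::ggplot(scree_curve(object),
                  ggplot2::aes(.data$k, .data$cumulative_ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "components k", y = "cumulative eigenvalue ratio")
}
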