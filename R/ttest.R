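#' Fraction of vertices with a significant two-sample t-test
#'
#' Runs a pointwise two-sample t-test (Welch by default; Student's pooled
#' variance optionally) at every vertex/column and returns the fraction of
#' vertices with `p < alpha`. Vertices where both groups have zero variance
#' are assigned `p = 1` with a warning. Used to compare the discriminative
#' power of residual features against raw pointwise thickness.
#'
#' @param group_a,group_b Numeric matrices, samples x vertices, with the
#'   same number of columns and at least 2 rows each.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Use Student's pooled-variance test instead of Welch.
#' @return List with `fraction`, `p_values`, and `t_statistics`.
#' @export
pointwise_ttest_fraction <- function(group_a, group_b, alpha = 0.05,
                                     var_equal = FALSE) {
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  if (ncol(A) != ncol(B)) stop("column counts differ", call. = FALSE)
  na <- nrow(A); nb <- nrow(B)
  if (na < 2L || nb < 2L) stop("need >= 2 samples per group", call. = FALSE)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2L, stats::var); vb <- apply(B, 2L, stats::var)
  degenerate <- va == 0 & vb == 0
  if (any(degenerate)) {
    warning(sprintf("%d vertex(es) with zero variance in both groups: p set to 1",
                    sum(degenerate)), call. = FALSE)
  }
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate] <- 1
  tstat[degenerate] <- 0
  list(fraction = mean(p < alpha), p_values = p, t_statistics = tstat)
}
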