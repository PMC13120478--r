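#' SVM kernel configuration
#'
#' Hyperparameters for the four standard SVM kernels: linear `x'y`,
#' polynomial `(gamma x'y + r)^d`, radial basis `exp(-gamma ||x-y||^2)`,
#' and sigmoid `tanh(gamma x'y + r)`. `gamma` must be positive for the
#' polynomial, RBF and sigmoid kernels.
#'
#' @param kernel One of `"linear"`, `"polynomial"`, `"rbf"`, `"sigmoid"`.
#' @param gamma Kernel shape parameter (> 0 where applicable).
#' @param r Kernel offset (polynomial, sigmoid).
#' @param degree Polynomial degree.
#' @param C Regularization parameter (> 0).
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(kernel = c("linear", "polynomial", "rbf", "sigmoid"),
                       gamma = 0.1, r = 0, degree = 3L, C = 1) {
  kernel <- match.arg(kernel)
  if (kernel != "linear" && (!is.numeric(gamma) || gamma <= 0)) {
    stop("gamma must be > 0 for ", kernel, " kernels", call. = FALSE)
  }
  if (!is.numeric(C) || C <= 0) stop("C must be > 0", call. = FALSE)
  structure(list(kernel = kernel, gamma = gamma, r = r,
                 degree = as.integer(degree), C = C),
            class = "svm_config")
}

#' Evaluate an SVM kernel between two feature vectors
#'
#' Implements the four standard kernel forms exactly; see [svm_config()].
#'
#' @param xi,xj Numeric vectors of equal length.
#' @param cfg An [svm_config()].
#' @return Scalar kernel value.
#' @export
svm_kernel <- function(xi, xj, cfg) {
  stopifnot(inherits(cfg, "svm_config"))
  if (length(xi) != length(xj)) stop("vectors must have equal length", call. = FALSE)
  switch(cfg$kernel,
    linear = sum(xi * xj),
    polynomial = (cfg$gamma * sum(xi * xj) + cfg$r)^cfg$degree,
    rbf = exp(-cfg$gamma * sum((xi - xj)^2)),
    sigmoid = tanh(cfg$gamma * sum(xi * xj) + cfg$r)
  )
}

# e1071 backend: fits an SVM under one svm_config. Labels are a factor with
# levels c("healthy", "MS"); MS is the positive class.
fit_svm <- function(features, labels, cfg) {
  features <- as.matrix(features)
  labels <- factor(labels, levels = c("healthy", "MS"))
  e1071::svm(
    x = features, y = labels,
    kernel = switch(cfg$kernel, rbf = "radial", cfg$kernel),
    gamma = if (cfg$kernel == "linear") 1 / ncol(features) else cfg$gamma,
    coef0 = cfg$r, degree = cfg$degree, cost = cfg$C,
    scale = FALSE, probability = FALSE
  )
}

# Hard predictions plus signed decision scores oriented so that larger
# scores favour the MS class.
predict_svm <- function(model, features) {
  features <- as.matrix(features)
  pr <- stats::predict(model, features, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  score <- as.numeric(dv[, 1L])
  # e1071 orients the decision value toward the first class in its header
  pos_first <- grepl("^MS", colnames(dv)[1L])
  if (!pos_first) score <- -score
  list(label = factor(as.character(pr), levels = c("healthy", "MS")),
       score = score)
}

#' Default hyperparameter grid
#'
#' Linear and RBF kernels over log-spaced `gamma` in 1e-3..1 and `C` in
#' 0.1..100, the neighborhood in which the linear kernel with small gamma
#' and moderate C is selected on this problem.
#'
#' @param kernels Kernel names to include.
#' @return List of [svm_config()] objects.
#' @export
default_svm_grid <- function(kernels = c("linear", "rbf")) {
  gammas <- 10^seq(-3, 0, by = 1)
  Cs <- 10^seq(-1, 2, by = 1)
  grid <- list()
  for (k in kernels) {
    if (k == "linear") {
      for (C in Cs) grid <- c(grid, list(svm_config("linear", C = C)))
    } else {
      for (g in gammas) for (C in Cs) {
        grid <- c(grid, list(svm_config(k, gamma = g, C = C)))
      }
    }
  }
  grid
}

#' Leave-one-out grid-search cross-validation
#'
#' For every candidate configuration, N models are trained each leaving one
#' sample out; the held-out sample's correctness is averaged into the CV
#' score (the fraction of held-out samples classified correctly). The
#' configuration with the highest CV score -- ties broken by grid order --
#' is refit on all N samples. If a fold's training split lacks one of the
#' classes, that fold is scored as incorrect with a warning.
#'
#' @param features N x k numeric feature matrix.
#' @param labels Length-N labels (`"healthy"`/`"MS"`).
#' @param grid Non-empty list of [svm_config()] objects.
#' @return List with `best_config`, `best_score`, `model` (refit on all
#'   rows), and `report` (tibble, one row per configuration).
#' @export
loo_grid_search <- function(features, labels, grid) {
  features <- as.matrix(features)
  labels <- factor(labels, levels = c("healthy", "MS"))
  N <- nrow(features)
  if (N < 2L) stop("need at least 2 samples", call. = FALSE)
  if (!length(grid)) stop("empty hyperparameter grid", call. = FALSE)
  scores <- purrr::map_dbl(grid, function(cfg) {
    correct <- purrr::map_lgl(seq_len(N), function(i) {
      tr_lab <- labels[-i]
      if (length(unique(tr_lab)) < 2L) {
        warning("a class is absent from a LOO training fold; fold scored incorrect",
                call. = FALSE)
        return(FALSE)
      }
      m <- fit_svm(features[-i, , drop = FALSE], tr_lab, cfg)
      pred <- predict_svm(m, features[i, , drop = FALSE])$label
      pred == labels[i]
    })
    mean(correct)
  })
  best <- which.max(scores)  # which.max takes the first maximum: grid order
  report <- dplyr::bind_rows(purrr::imap(grid, function(cfg, j) {
    tibble::tibble(kernel = cfg$kernel, gamma = cfg$gamma, r = cfg$r,
                   degree = cfg$degree, C = cfg$C, cv_score = scores[j])
  }))
  list(best_config = grid[[best]], best_score = scores[best],
       model = fit_svm(features, labels, grid[[best]]),
       report = report)
}
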