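#' Study configuration for the F-shape pipeline
#'
#' Bundles every knob of a full run: the synthetic cohort, the ROI, the two
#' mesh densities (4 percent for subjects, 4.5 percent for the template),
#' the registration configuration, the PCA rule, the SVM grid and the
#' train/test split sizes. `desk_study_config()` is a reduced-lattice
#' preset (150 px wide grids, ~400-vertex subject meshes, frozen template
#' geometry, capped iterations) sized for interactive runs and the test
#' suite; `study_config()` with defaults reproduces the full-resolution
#' geometry.
#'
#' @param seed Master seed: drives cohort generation and the split.
#' @param cohort A [cohort_config()].
#' @param roi A [roi_frame()].
#' @param subject_fraction,template_fraction Mesh decimation fractions.
#' @param reg A [registration_config()].
#' @param atlas_outer Outer-iteration cap for atlas estimation.
#' @param n_train_healthy,n_train_ms Training-set sizes (remainder tests).
#' @param svm_grid List of [svm_config()]s for the LOO grid search.
#' @param pca_gain_threshold Scree flattening threshold (see [fit_pca()]).
#' @param pca_rule `"auto"` (PCA only when feature dimension exceeds the
#'   sample count), `"always"`, or `"never"`.
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 1L,
                         cohort = cohort_config(seed = seed),
                         roi = roi_frame(),
                         subject_fraction = 0.04,
                         template_fraction = 0.045,
                         reg = registration_config(seed = seed),
                         atlas_outer = reg$max_iter,
                         n_train_healthy = 28L, n_train_ms = 26L,
                         svm_grid = default_svm_grid(),
                         pca_gain_threshold = 0.01,
                         pca_rule = c("auto", "always", "never")) {
  structure(
    list(seed = as.integer(seed), cohort = cohort, roi = roi,
         subject_fraction = subject_fraction,
         template_fraction = template_fraction,
         reg = reg, atlas_outer = as.integer(atlas_outer),
         n_train_healthy = as.integer(n_train_healthy),
         n_train_ms = as.integer(n_train_ms),
         svm_grid = svm_grid, pca_gain_threshold = pca_gain_threshold,
         pca_rule = match.arg(pca_rule)),
    class = "study_config"
  )
}

#' @rdname study_config
#' @param width Lattice width (px) of the reduced grids.
#' @param ... Overrides passed on to [study_config()].
#' @export
desk_study_config <- function(seed = 1L, width = 150L, ...) {
  factor <- width / 461
  cohort <- cohort_config(grid_shape = c(width, width), seed = seed)
  reg <- registration_config(shoot_steps = 5L, max_iter = 5L,
                             sigma_sig = 60, p_every = 3L,
                             update_geometry = FALSE, seed = seed)
  study_config(seed = seed, cohort = cohort,
               roi = scale_roi(roi_frame(), factor),
               reg = reg, atlas_outer = 4L, ...)
}

#' Build a shared-connectivity F-shape set from subject records
#'
#' Part (a) of the pipeline: orientation-normalize every record, plan the
#' decimated triangular mesh on the ROI once (connectivity is a function of
#' the ROI and fraction only, so it is shared by construction), assemble
#' each eye's F-shape (subject ILM as geometry, subject GCIPL as signal)
#' and convert to mm.
#'
#' @param records List of [subject_record()]s.
#' @param roi A [roi_frame()].
#' @param fraction Mesh decimation fraction.
#' @param s Optional ideal cell side override (see [plan_square_grid()]).
#' @return List with `fshapes` (mm units), `mesh_template` (lattice units),
#'   `labels`.
#' @export
build_fshape_set <- function(records, roi, fraction, s = NULL) {
  records <- purrr::map(records, normalize_orientation)
  mesh_template <- build_tri_mesh(roi, records[[1]]$ilm, fraction, s)
  fshapes <- purrr::map(records, function(r) {
    fshape_to_mm(assemble_fshape(r, mesh_template))
  })
  list(fshapes = fshapes, mesh_template = mesh_template,
       labels = purrr::map_chr(records, "label"))
}

# hypertemplate: template-density mesh on the mean ILM surface of the
# training eyes, zero signal
build_hypertemplate <- function(records, roi, fraction, s = NULL) {
  records <- purrr::map(records, normalize_orientation)
  ilm_mean <- records[[1]]$ilm
  acc <- Reduce(`+`, purrr::map(records, ~.x$ilm$values)) / length(records)
  ilm_mean$values <- acc
  mesh <- build_tri_mesh(roi, ilm_mean, fraction, s)
  fshape_to_mm(fshape(mesh, numeric(nrow(mesh$vertices))))
}

#' Train the F-shape classifier
#'
#' Part (b) of the pipeline: assemble training F-shapes at the subject
#' density, estimate the mean-template atlas starting from a zero-signal
#' hypertemplate at the template density, then re-register every training
#' eye to the frozen final template with exactly the operator used at test
#' time and take the residual-thickness features `f_m - f_i~` from those
#' registrations (so training and test features come from one
#' distribution). Features are reduced by PCA (by default only when the
#' feature dimension exceeds the sample count) and an SVM is selected by
#' leave-one-out grid search.
#'
#' @param records Training [subject_record()]s.
#' @param config A [study_config()].
#' @return An object of class `fshape_fit`.
#' @export
fit_fshape_classifier <- function(records, config) {
  fs <- build_fshape_set(records, config$roi, config$subject_fraction)
  hyper <- build_hypertemplate(records, config$roi, config$template_fraction)
  atlas <- estimate_atlas(fs$fshapes, hyper, config$reg,
                          max_outer = config$atlas_outer)
  rereg <- purrr::map(fs$fshapes, function(f) {
    register_subject(atlas$template, f, config$reg)$registered
  })
  res <- compute_residuals(list(template = atlas$template,
                                registered = rereg),
                           labels = fs$labels)
  use_pca <- switch(config$pca_rule,
                    auto = ncol(res$matrix) > nrow(res$matrix),
                    always = TRUE, never = FALSE)
  pca <- NULL
  feats <- res$matrix
  if (use_pca) {
    pca <- fit_pca(res$matrix, gain_threshold = config$pca_gain_threshold)
    feats <- pca_transform(pca, res$matrix)
  }
  gs <- loo_grid_search(feats, fs$labels, config$svm_grid)
  structure(
    list(mesh_template = fs$mesh_template, template = atlas$template,
         atlas = atlas, residuals = res, pca = pca,
         train_features = feats, train_labels = fs$labels,
         svm = gs, config = config),
    class = "fshape_fit"
  )
}

#' @export
print.fshape_fit <- function(x, ...) {
  cat(sprintf(
    "<fshape_fit> %d training eyes, %d residual features%s; best CV score %.3f (%s kernel)\n",
    nrow(x$residuals$matrix), ncol(x$residuals$matrix),
    if (!is.null(x$pca)) sprintf(" -> %d PCs", x$pca$k) else "",
    x$svm$best_score, x$svm$best_config$kernel
  ))
  invisible(x)
}

#' @rdname fit_fshape_classifier
#' @param x An `fshape_fit`.
#' @param ... Unused.
#' @export
glance.fshape_fit <- function(x, ...) {
  tibble::tibble(
    n_train = nrow(x$residuals$matrix),
    n_features = ncol(x$residuals$matrix),
    n_components = if (is.null(x$pca)) NA_integer_ else x$pca$k,
    cv_score = x$svm$best_score,
    kernel = x$svm$best_config$kernel,
    C = x$svm$best_config$C,
    atlas_iterations = length(x$atlas$objective_trace) - 1L
  )
}

#' Classify eyes with a trained F-shape classifier
#'
#' Part (c) of the pipeline: each eye's F-shape is assembled on the stored
#' subject mesh, registered to the frozen mean template (template held
#' fixed; only the subject's momenta and signal increments are optimized),
#' its residual is projected with the stored PCA, and the stored SVM
#' predicts. Nothing trained in part (b) is modified.
#'
#' @param fit An `fshape_fit`.
#' @param records [subject_record()]s to classify.
#' @param evaluate Compute [evaluate_classifier()] metrics against the
#'   records' labels.
#' @return List with `predictions` (tibble), `residuals` (matrix), and
#'   `metrics` (an `eval_metrics`, when `evaluate = TRUE`).
#' @export
classify_eyes <- function(fit, records, evaluate = TRUE) {
  stopifnot(inherits(fit, "fshape_fit"))
  records <- purrr::map(records, normalize_orientation)
  resid <- purrr::map(records, function(r) {
    fs <- fshape_to_mm(assemble_fshape(r, fit$mesh_template))
    reg <- register_subject(fit$template, fs, fit$config$reg)
    fit$template$signal - reg$registered$signal
  })
  resid <- do.call(rbind, resid)
  feats <- if (!is.null(fit$pca)) pca_transform(fit$pca, resid) else resid
  pr <- predict_svm(fit$svm$model, feats)
  labels <- purrr::map_chr(records, "label")
  out <- list(
    predictions = tibble::tibble(
      eye_id = purrr::map_chr(records, "eye_id"),
      truth = labels, predicted = as.character(pr$label), score = pr$score),
    residuals = resid
  )
  if (evaluate) {
    out$metrics <- evaluate_classifier(fit$svm$model, feats, labels)
  }
  out
}

#' ETDRS sectoral baseline classifier
#'
#' Computes the nine sector-mean features for every eye (no PCA: nine
#' features), selects an SVM by the same leave-one-out grid search, and
#' evaluates on the test eyes. The same split as the F-shape run gives a
#' head-to-head comparison.
#'
#' @param train_records,test_records [subject_record()]s.
#' @param config A [study_config()] (uses the cohort's fovea center and the
#'   SVM grid).
#' @return List with `features_train`, `features_test`, `svm`
#'   (grid-search result), `metrics`.
#' @export
fit_sectoral_classifier <- function(train_records, test_records, config) {
  center <- config$cohort$fovea_center
  pitch <- config$cohort$pixel_pitch
  shape <- config$cohort$grid_shape
  eg <- build_etdrs_grid(shape, pitch, center)
  feat <- function(records) {
    records <- purrr::map(records, normalize_orientation)
    do.call(rbind, purrr::map(records, ~sector_means(.x$thickness, eg)))
  }
  Xtr <- feat(train_records); Xte <- feat(test_records)
  ytr <- purrr::map_chr(train_records, "label")
  yte <- purrr::map_chr(test_records, "label")
  gs <- loo_grid_search(Xtr, ytr, config$svm_grid)
  list(features_train = Xtr, features_test = Xte, svm = gs,
       metrics = evaluate_classifier(gs$model, Xte, yte))
}

#' Run the full synthetic study end to end
#'
#' Simulates a cohort, splits it, trains the F-shape classifier on the
#' training eyes, classifies the held-out eyes, and runs the ETDRS sectoral
#' baseline on the identical split.
#'
#' @param config A [study_config()] (e.g. [desk_study_config()]).
#' @param sectoral Also run the sectoral baseline.
#' @return List with `fit`, `test` (classification output), `sectoral`,
#'   `split`, `records`.
#' @export
run_fshape_study <- function(config = desk_study_config(), sectoral = TRUE) {
  recs <- simulate_cohort(config$cohort)
  labels <- purrr::map_chr(recs, "label")
  sp <- make_split(labels, config$n_train_healthy, config$n_train_ms,
                   seed = config$seed)
  fit <- fit_fshape_classifier(recs[sp$train], config)
  test <- classify_eyes(fit, recs[sp$test])
  out <- list(fit = fit, test = test, split = sp, records = recs)
  if (sectoral) {
    out$sectoral <- fit_sectoral_classifier(recs[sp$train], recs[sp$test],
                                            config)
  }
  out
}

#' Compare residual-feature and raw-thickness discriminability
#'
#' Runs the atlas on all eyes of a simulated cohort, then performs a
#' pointwise two-sample t-test between the groups twice: on the residual
#' features (template vertices) and on the raw pointwise thickness sampled
#' at the subject mesh vertices. Returns the fraction of vertices with
#' `p < alpha` for each feature type. Anatomical jitter in the cohort
#' degrades the raw pointwise comparison; registration re-aligns the eyes,
#' which is the rationale for classifying on residuals.
#'
#' @param config A [study_config()].
#' @param alpha Significance level.
#' @return One-row tibble with `fraction_residual` and `fraction_raw`.
#' @export
residual_significance_study <- function(config, alpha = 0.05) {
  recs <- simulate_cohort(config$cohort)
  labels <- purrr::map_chr(recs, "label")
  fs <- build_fshape_set(recs, config$roi, config$subject_fraction)
  hyper <- build_hypertemplate(recs, config$roi, config$template_fraction)
  atlas <- estimate_atlas(fs$fshapes, hyper, config$reg,
                          max_outer = config$atlas_outer)
  res <- compute_residuals(atlas, labels = labels)
  raw <- do.call(rbind, purrr::map(fs$fshapes, "signal"))
  h <- labels == "healthy"
  fr_res <- pointwise_ttest_fraction(res$matrix[h, , drop = FALSE],
                                     res$matrix[!h, , drop = FALSE],
                                     alpha)$fraction
  fr_raw <- pointwise_ttest_fraction(raw[h, , drop = FALSE],
                                     raw[!h, , drop = FALSE],
                                     alpha)$fraction
  tibble::tibble(fraction_residual = fr_res, fraction_raw = fr_raw)
}

#' Write a simulated cohort to disk
#'
#' Writes each eye's thickness and ILM grids as binary containers plus the
#' dataset manifest CSV.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  recs <- simulate_cohort(config$cohort)
  man <- attr(recs, "manifest")
  man$thickness_path <- sprintf("%s_gcipl.bin", man$eye_id)
  man$ilm_path <- sprintf("%s_ilm.bin", man$eye_id)
  purrr::pwalk(list(recs, man$thickness_path, man$ilm_path),
               function(r, tp, ip) {
                 write_grid(r$thickness, file.path(out_dir, tp), "binary_container")
                 write_grid(r$ilm, file.path(out_dir, ip), "binary_container")
               })
  path <- file.path(out_dir, "manifest.csv")
  write_manifest(man, path)
  invisible(path)
}
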