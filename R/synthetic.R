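#' Synthetic cohort configuration
#'
#' Parameters of the synthetic GCIPL/ILM generator. The class means and
#' standard deviations default to the published group statistics for
#' macular GCIPL (healthy 75.9 (6.2) um, MS 62.9 (5.4) um across eyes); MS
#' thinning is confined to a horseshoe-shaped annulus around the fovea with
#' an angular gap on the temporal side. Between-eye variability enters at
#' the subject level (a scalar thickness multiplier, so map means are
#' Normal(class mean, class SD)), on top of a smooth random anatomical
#' warp and i.i.d. pixel noise.
#'
#' @param n_healthy_eyes,n_ms_eyes Cohort sizes (default 37 and 35).
#' @param grid_shape `c(height, width)` in pixels.
#' @param pixel_pitch mm per pixel; defaults to 6 mm / width.
#' @param healthy_mean,healthy_sd,ms_mean,ms_sd Class map-mean statistics
#'   (um).
#' @param fovea_center 0-based lattice `c(x, y)` of the fovea; defaults to
#'   the map center.
#' @param horseshoe_inner_mm,horseshoe_outer_mm Annulus radii (mm).
#' @param gap_center_deg,gap_width_deg Angular gap direction (180 = the
#'   temporal side under the right-eye convention used here) and width.
#' @param taper_mm,taper_deg Smooth taper widths at the region edges.
#' @param anatomy_jitter Smooth-deformation amplitude (mm, RMS displacement).
#' @param jitter_corr_mm Correlation length of the deformation field (mm).
#' @param noise_sd Pixel measurement noise SD (um).
#' @param ilm_dome_um ILM dome height over the scan field (um).
#' @param seed Generator seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_healthy_eyes = 37L, n_ms_eyes = 35L,
                          grid_shape = c(461L, 461L), pixel_pitch = NULL,
                          healthy_mean = 75.9, healthy_sd = 6.2,
                          ms_mean = 62.9, ms_sd = 5.4,
                          fovea_center = NULL,
                          horseshoe_inner_mm = 0.5, horseshoe_outer_mm = 2.5,
                          gap_center_deg = 180, gap_width_deg = 90,
                          taper_mm = 0.2, taper_deg = 10,
                          anatomy_jitter = 0.1, jitter_corr_mm = 1.5,
                          noise_sd = 2, ilm_dome_um = 300, seed = 1L) {
  if (is.null(pixel_pitch)) pixel_pitch <- 6 / grid_shape[2]
  if (is.null(fovea_center)) {
    fovea_center <- c((grid_shape[2] - 1) / 2, (grid_shape[1] - 1) / 2)
  }
  stopifnot(n_healthy_eyes >= 0, n_ms_eyes >= 0,
            healthy_sd >= 0, ms_sd >= 0, noise_sd >= 0,
            healthy_mean > 0, ms_mean > 0, anatomy_jitter >= 0)
  structure(
    list(n_healthy_eyes = as.integer(n_healthy_eyes),
         n_ms_eyes = as.integer(n_ms_eyes),
         grid_shape = as.integer(grid_shape), pixel_pitch = pixel_pitch,
         healthy_mean = healthy_mean, healthy_sd = healthy_sd,
         ms_mean = ms_mean, ms_sd = ms_sd,
         fovea_center = fovea_center,
         horseshoe_inner_mm = horseshoe_inner_mm,
         horseshoe_outer_mm = horseshoe_outer_mm,
         gap_center_deg = gap_center_deg, gap_width_deg = gap_width_deg,
         taper_mm = taper_mm, taper_deg = taper_deg,
         anatomy_jitter = anatomy_jitter, jitter_corr_mm = jitter_corr_mm,
         noise_sd = noise_sd, ilm_dome_um = ilm_dome_um,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# radius (mm) and angle (deg) fields around the fovea center
polar_fields <- function(grid_shape, pixel_pitch, center) {
  h <- grid_shape[1]; wd <- grid_shape[2]
  x <- matrix(rep(0:(wd - 1), each = h), h, wd) - center[1]
  y <- matrix(rep(0:(h - 1), times = wd), h, wd) - center[2]
  list(r = sqrt(x^2 + y^2) * pixel_pitch, theta = atan2(y, x) * 180 / pi)
}

#' Deterministic healthy GCIPL thickness template
#'
#' Radial foveal-pit topography: near-zero thickness at the foveal center,
#' an annular peak near 1 mm radius (`r^2 exp(-r / 0.5)` with a small
#' floor), decaying toward the periphery, rescaled so the map mean equals
#' `target_mean`.
#'
#' @param grid_shape `c(height, width)` pixels.
#' @param pixel_pitch mm per pixel.
#' @param target_mean Desired map mean (um).
#' @param center Fovea lattice position `c(x, y)`; defaults to map center.
#' @return A [thickness_grid()].
#' @export
healthy_profile <- function(grid_shape, pixel_pitch, target_mean = 75.9,
                            center = NULL) {
  if (is.null(center)) {
    center <- c((grid_shape[2] - 1) / 2, (grid_shape[1] - 1) / 2)
  }
  pf <- polar_fields(grid_shape, pixel_pitch, center)
  shape <- 0.004 + pf$r^2 * exp(-pf$r / 0.5)
  vals <- shape * (target_mean / mean(shape))
  thickness_grid(vals, pixel_pitch = pixel_pitch, layer_tag = "GCIPL")
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# horseshoe membership weight in [0, 1]: radial annulus band with smooth
# taper, times an angular factor that vanishes inside the gap
horseshoe_weight <- function(cohort) {
  pf <- polar_fields(cohort$grid_shape, cohort$pixel_pitch,
                     cohort$fovea_center)
  w_in <- smoothstep((pf$r - cohort$horseshoe_inner_mm) / cohort$taper_mm)
  w_out <- smoothstep((cohort$horseshoe_outer_mm - pf$r) / cohort$taper_mm)
  d <- abs(((pf$theta - cohort$gap_center_deg + 180) %% 360) - 180)
  w_ang <- smoothstep((d - cohort$gap_width_deg / 2) / cohort$taper_deg)
  w_in * w_out * w_ang
}

#' Apply the MS thinning effect to a healthy template
#'
#' Multiplies thickness inside the horseshoe annulus (excluding the angular
#' gap, with smooth tapers at all edges) by a spatially varying factor
#' calibrated so the map mean drops from the healthy template's mean to
#' `cohort$ms_mean`. Pixels outside the horseshoe (including the gap) are
#' unchanged.
#'
#' @param healthy A healthy-template [thickness_grid()].
#' @param cohort A [cohort_config()].
#' @return A [thickness_grid()] with mean `cohort$ms_mean`.
#' @export
apply_ms_effect <- function(healthy, cohort) {
  stopifnot(inherits(healthy, "thickness_grid"))
  m <- horseshoe_weight(cohort)
  drop_needed <- mean(healthy$values) - cohort$ms_mean
  denom <- mean(healthy$values * m)
  if (denom <= 0) stop("horseshoe region carries no thickness", call. = FALSE)
  depth <- drop_needed / denom
  if (depth > 1) {
    stop("infeasible MS effect: thinning factor would go negative",
         call. = FALSE)
  }
  vals <- healthy$values * (1 - depth * m)
  thickness_grid(vals, pixel_pitch = healthy$pixel_pitch,
                 eye_side = healthy$eye_side, layer_tag = healthy$layer_tag)
}

# separable Gaussian smoothing of a matrix (reflective edges via
# renormalized truncated kernel)
gauss_smooth <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  smooth1 <- function(mat) {
    n <- nrow(mat)
    idx <- outer(seq_len(n), -half:half, "+")
    idx <- pmin(pmax(idx, 1L), n)           # clamp at borders
    out <- matrix(0, n, ncol(mat))
    for (j in seq_along(k)) out <- out + k[j] * mat[idx[, j], , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(m))))
}

# smooth random displacement field, RMS-normalized to `amp_px` pixels
random_displacement <- function(grid_shape, sigma_px, amp_px) {
  draw <- function() {
    z <- matrix(stats::rnorm(prod(grid_shape)), grid_shape[1], grid_shape[2])
    s <- gauss_smooth(z, sigma_px)
    rms <- sqrt(mean(s^2))
    if (rms == 0) s else s / rms * amp_px
  }
  list(dx = draw(), dy = draw())
}

# backward bilinear warp: out(x, y) = in(x + dx, y + dy), border-clamped
warp_bilinear <- function(values, dx, dy) {
  h <- nrow(values); wd <- ncol(values)
  X <- matrix(rep(0:(wd - 1), each = h), h, wd) + dx
  Y <- matrix(rep(0:(h - 1), times = wd), h, wd) + dy
  X <- pmin(pmax(X, 0), wd - 1); Y <- pmin(pmax(Y, 0), h - 1)
  x0 <- floor(X); y0 <- floor(Y)
  x1 <- pmin(x0 + 1, wd - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- X - x0; fy <- Y - y0
  v <- function(yy, xx) values[cbind(as.vector(yy) + 1, as.vector(xx) + 1)]
  out <- (1 - fx) * (1 - fy) * v(y0, x0) + fx * (1 - fy) * v(y0, x1) +
    (1 - fx) * fy * v(y1, x0) + fx * fy * v(y1, x1)
  matrix(out, h, wd)
}

ilm_dome <- function(cohort) {
  pf <- polar_fields(cohort$grid_shape, cohort$pixel_pitch,
                     cohort$fovea_center)
  rmax <- max(pf$r)
  cohort$ilm_dome_um * (1 - (pf$r / rmax)^2)
}

#' Draw one synthetic eye
#'
#' The subject map is the class template scaled by a subject-level factor
#' drawn so that map means are Normal(class mean, class SD), warped by a
#' smooth random lattice deformation (Gaussian-filtered displacement field
#' of RMS amplitude `anatomy_jitter` mm), with i.i.d. Normal pixel noise
#' clipped at zero. The ILM surface is a smooth dome warped by the same
#' deformation. Uses the current RNG state (callers seed it; see
#' [simulate_cohort()]).
#'
#' @param cohort A [cohort_config()].
#' @param label `"healthy"` or `"MS"`.
#' @param subject_id,eye_id Identifiers.
#' @param side `"right"` or `"left"`; left eyes are stored mirrored (native
#'   orientation), to be normalized downstream.
#' @return A [subject_record()] with attribute `ground_truth` (the subject
#'   scalar and displacement field).
#' @export
sample_subject <- function(cohort, label, subject_id = "S1", eye_id = "E1",
                           side = "right") {
  label <- match.arg(label, c("healthy", "MS"))
  templ <- healthy_profile(cohort$grid_shape, cohort$pixel_pitch,
                           cohort$healthy_mean, cohort$fovea_center)
  class_mean <- cohort$healthy_mean; class_sd <- cohort$healthy_sd
  if (label == "MS") {
    templ <- apply_ms_effect(templ, cohort)
    class_mean <- cohort$ms_mean; class_sd <- cohort$ms_sd
  }
  target <- stats::rnorm(1, class_mean, class_sd)
  vals <- templ$values * (target / class_mean)
  sigma_px <- cohort$jitter_corr_mm / cohort$pixel_pitch
  amp_px <- cohort$anatomy_jitter / cohort$pixel_pitch
  disp <- if (amp_px > 0) {
    random_displacement(cohort$grid_shape, sigma_px, amp_px)
  } else {
    list(dx = matrix(0, cohort$grid_shape[1], cohort$grid_shape[2]),
         dy = matrix(0, cohort$grid_shape[1], cohort$grid_shape[2]))
  }
  if (amp_px > 0) vals <- warp_bilinear(vals, disp$dx, disp$dy)
  if (cohort$noise_sd > 0) {
    vals <- vals + matrix(stats::rnorm(length(vals), 0, cohort$noise_sd),
                          nrow(vals), ncol(vals))
  }
  vals <- pmax(vals, 0)
  ilm_vals <- ilm_dome(cohort)
  if (amp_px > 0) ilm_vals <- warp_bilinear(ilm_vals, disp$dx, disp$dy)
  th <- thickness_grid(vals, pixel_pitch = cohort$pixel_pitch,
                       layer_tag = "GCIPL")
  il <- thickness_grid(ilm_vals, pixel_pitch = cohort$pixel_pitch,
                       layer_tag = "ILM_elevation")
  if (side == "left") {
    th <- mirror_grid(th); il <- mirror_grid(il)
    th$eye_side <- "left"; il$eye_side <- "left"
  }
  rec <- subject_record(subject_id, eye_id, label, th, il)
  attr(rec, "ground_truth") <- list(target_mean = target, dx = disp$dx,
                                    dy = disp$dy)
  rec
}

#' Generate a full synthetic cohort
#'
#' Draws `n_healthy_eyes` + `n_ms_eyes` eyes (sides alternating
#' right/left), fully reproducible from `cohort$seed`.
#'
#' @param cohort A [cohort_config()].
#' @return List of [subject_record()]s with a `manifest` attribute (tibble
#'   of ids, labels and sides).
#' @export
simulate_cohort <- function(cohort) {
  set.seed(cohort$seed)
  specs <- tibble::tibble(
    label = c(rep("healthy", cohort$n_healthy_eyes),
              rep("MS", cohort$n_ms_eyes))
  )
  n <- nrow(specs)
  if (n == 0L) {
    out <- list()
    attr(out, "manifest") <- tibble::tibble(
      subject_id = character(), eye_id = character(),
      label = character(), side = character())
    return(out)
  }
  specs$subject_id <- sprintf("S%03d", seq_len(n))
  specs$eye_id <- sprintf("%s_E1", specs$subject_id)
  specs$side <- rep(c("right", "left"), length.out = n)
  recs <- purrr::pmap(specs, function(label, subject_id, eye_id, side) {
    sample_subject(cohort, label, subject_id, eye_id, side)
  })
  attr(recs, "manifest") <- specs[, c("subject_id", "eye_id", "label", "side")]
  recs
}

#' Split a cohort into training and test sets
#'
#' Seeded random selection of `n_train_healthy` healthy and `n_train_ms` MS
#' eyes for training; all remaining eyes form the test set.
#'
#' @param labels Per-eye labels (`"healthy"`/`"MS"`).
#' @param n_train_healthy,n_train_ms Training counts (defaults 28 and 26).
#' @param seed Split seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
make_split <- function(labels, n_train_healthy = 28L, n_train_ms = 26L,
                       seed = 1L) {
  idx_h <- which(labels == "healthy"); idx_m <- which(labels == "MS")
  if (n_train_healthy > length(idx_h) || n_train_ms > length(idx_m)) {
    stop("training set oversubscribes the cohort", call. = FALSE)
  }
  set.seed(seed)
  tr <- c(sample(idx_h, n_train_healthy), sample(idx_m, n_train_ms))
  list(train = sort(tr), test = sort(setdiff(seq_along(labels), tr)))
}
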