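#' Build the ETDRS nine-sector macular grid
#'
#' Concentric discs of 1, 3 and 6 mm diameter centred on the fovea: the
#' central 1 mm disc (CF), and inner (0.5-1.5 mm radius) and outer
#' (1.5-3 mm) rings each split into superior/nasal/inferior/temporal
#' quadrants by the two diagonal lines at +-45 degrees through the center.
#' Pixels are assigned by center-of-pixel radius, ties at a band boundary
#' going to the inner band; nasal is the +x side and superior the +y side
#' (right-eye convention). Sectors are pairwise disjoint and partition the
#' 6 mm disc clipped to the grid.
#'
#' @param grid_shape `c(height, width)` in pixels.
#' @param pixel_pitch mm per pixel.
#' @param center Fovea position, 0-based lattice `c(x, y)`; defaults to the
#'   map center.
#' @param diameters Disc diameters in mm (central, inner, outer).
#' @return An object of class `etdrs_grid`: `labels` (height x width
#'   character matrix, `NA` outside the 6 mm disc), `sector_masks` (named
#'   list of 9 logical matrices), `center`, `pixel_pitch`.
#' @export
build_etdrs_grid <- function(grid_shape, pixel_pitch,
                             center = NULL, diameters = c(1, 3, 6)) {
  h <- grid_shape[1]; wd <- grid_shape[2]
  if (is.null(center)) center <- c((wd - 1) / 2, (h - 1) / 2)
  if (center[1] < 0 || center[1] > wd - 1 || center[2] < 0 || center[2] > h - 1) {
    stop("fovea center outside grid", call. = FALSE)
  }
  radii <- diameters / 2
  x <- matrix(rep(0:(wd - 1), each = h), h, wd) - center[1]
  y <- matrix(rep(0:(h - 1), times = wd), h, wd) - center[2]
  r <- sqrt(x^2 + y^2) * pixel_pitch
  edge_mm <- (min(center[1], wd - 1 - center[1],
                  center[2], h - 1 - center[2]) + 0.5) * pixel_pitch
  if (edge_mm < radii[3]) {
    warning("6 mm disc does not fit the grid; sectors are clipped",
            call. = FALSE)
  }
  # quadrants bounded by the +-45 degree diagonals; pixels exactly on a
  # diagonal go to the superior/inferior pair, which keeps sector means
  # equivariant under the horizontal (nasal-temporal) mirror
  quad <- ifelse(abs(y) >= abs(x),
                 ifelse(y >= 0, "S", "I"),
                 ifelse(x > 0, "N", "T"))
  labels <- matrix(NA_character_, h, wd)
  in_cf <- r <= radii[1]
  in_inner <- r > radii[1] & r <= radii[2]
  in_outer <- r > radii[2] & r <= radii[3]
  labels[in_cf] <- "CF"
  labels[in_inner] <- paste0("I", quad[in_inner])
  labels[in_outer] <- paste0("O", quad[in_outer])
  sector_names <- c("CF", "IS", "IN", "II", "IT", "OS", "ON", "OI", "OT")
  masks <- lapply(sector_names, function(s) !is.na(labels) & labels == s)
  names(masks) <- sector_names
  structure(
    list(labels = labels, sector_masks = masks, center = center,
         pixel_pitch = pixel_pitch, diameters = diameters),
    class = "etdrs_grid"
  )
}

#' @export
print.etdrs_grid <- function(x, ...) {
  cat(sprintf("<etdrs_grid> center (%.1f, %.1f), pitch %.4g mm/px, %d in-disc pixels\n",
              x$center[1], x$center[2], x$pixel_pitch, sum(!is.na(x$labels))))
  invisible(x)
}

#' Sector mean thicknesses over the ETDRS grid
#'
#' Arithmetic mean of the thickness map over each of the nine sector masks,
#' in the fixed order CF, IS, IN, II, IT, OS, ON, OI, OT. These nine values
#' are the sectoral classifier features. An empty (fully clipped) sector is
#' reported as `NA` with a warning.
#'
#' @param thickness A [thickness_grid()] matching the grid shape.
#' @param grid An [build_etdrs_grid()] result.
#' @return A named numeric vector of 9 sector means (um).
#' @export
sector_means <- function(thickness, grid) {
  stopifnot(inherits(thickness, "thickness_grid"), inherits(grid, "etdrs_grid"))
  if (!all(dim(thickness$values) == dim(grid$labels))) {
    stop("thickness map and ETDRS grid shapes differ", call. = FALSE)
  }
  out <- vapply(grid$sector_masks, function(m) {
    if (!any(m)) return(NA_real_)
    mean(thickness$values[m])
  }, numeric(1))
  if (anyNA(out)) {
    warning("empty ETDRS sector(s) after clipping: ",
            paste(names(out)[is.na(out)], collapse = ", "), call. = FALSE)
  }
  out
}
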