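#' Triangular surface mesh on the ROI lattice
#'
#' Vertices carry 3D coordinates (x, y in lattice units; z elevation in
#' micrometres) plus their originating lattice point; faces are vertex-index
#' triples. Constructed by [build_tri_mesh()].
#'
#' @param vertices Numeric n x 3 matrix (x, y, z).
#' @param faces Integer F x 3 matrix of 1-based vertex indices.
#' @param lattice Integer n x 2 matrix of 0-based lattice (x, y) coordinates.
#' @param pixel_pitch Lattice spacing in mm per pixel.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, lattice, pixel_pitch) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face references an invalid vertex", call. = FALSE)
  }
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3])) {
    stop("degenerate face with repeated vertex", call. = FALSE)
  }
  structure(
    list(vertices = vertices, faces = faces,
         lattice = as.matrix(lattice), pixel_pitch = pixel_pitch),
    class = "tri_mesh"
  )
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces, pitch %.4g mm/px\n",
              nrow(x$vertices), nrow(x$faces), x$pixel_pitch))
  invisible(x)
}

#' Functional shape: a mesh with a per-vertex scalar signal
#'
#' The pair (X, f) of a triangulated surface and the thickness signal living
#' on its vertices; the unit of analysis for atlas registration.
#'
#' @param mesh A [tri_mesh()].
#' @param signal Numeric vector, one finite value per vertex (micrometres).
#' @return An object of class `fshape`.
#' @export
fshape <- function(mesh, signal) {
  stopifnot(inherits(mesh, "tri_mesh"))
  signal <- as.numeric(signal)
  if (length(signal) != nrow(mesh$vertices)) {
    stop("signal length must equal vertex count", call. = FALSE)
  }
  if (any(!is.finite(signal))) stop("signal must be finite", call. = FALSE)
  structure(list(mesh = mesh, signal = signal), class = "fshape")
}

#' @export
print.fshape <- function(x, ...) {
  cat(sprintf("<fshape> %d vertices, %d faces; signal [%.1f, %.1f] um\n",
              nrow(x$mesh$vertices), nrow(x$mesh$faces),
              min(x$signal), max(x$signal)))
  invisible(x)
}

#' Plan the decimated square grid over an ROI
#'
#' To keep roughly `fraction` of the ROI lattice points as mesh vertices, the
#' outer rectangle is divided into near-square cells of ideal side
#' `s = 1 / sqrt(fraction)` lattice units (one retained vertex per `s^2`
#' original points; s = 5 at 4 percent, s ~ 4.7 at 4.5 percent). Each axis is
#' cut into `round(span / s)` equal ideal intervals whose cut positions are
#' snapped to the nearest lattice integer, so all cell sides are
#' `floor(span/n)` or `ceil(span/n)` lattice units -- 4 or 5 at the default
#' densities -- and the first and last cuts coincide with the outer rectangle
#' edges.
#'
#' @param roi A [roi_frame()].
#' @param fraction Target retained fraction of ROI lattice points, in (0, 1).
#' @param s Ideal cell side in lattice units; defaults to `1/sqrt(fraction)`.
#' @return List with integer vectors `x_cuts` and `y_cuts`.
#' @export
plan_square_grid <- function(roi, fraction, s = NULL) {
  stopifnot(inherits(roi, "roi_frame"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
        fraction <= 0 || fraction >= 1) {
    stop("fraction must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(s)) s <- 1 / sqrt(fraction)
  if (s < 2) stop("ideal cell side below 2 lattice units; fraction too large",
                  call. = FALSE)
  o <- roi$outer
  axis_cuts <- function(lo, hi) {
    span <- hi - lo
    n <- max(1L, as.integer(round(span / s)))
    cuts <- as.integer(round(seq(lo, hi, length.out = n + 1L)))
    unique(cuts)
  }
  list(x_cuts = axis_cuts(o[1], o[2]), y_cuts = axis_cuts(o[3], o[4]))
}

#' Build the decimated triangular mesh over an ROI
#'
#' Cells of the planned square grid that overlap the ROI's inner open
#' interior are dropped whole (never clipped), every retained cell is split
#' into two right triangles along its main diagonal (lower-left to
#' upper-right), and each vertex takes its z coordinate from `surface` at its
#' lattice point.
#'
#' @inheritParams plan_square_grid
#' @param surface A [thickness_grid()] covering the ROI (typically the ILM
#'   elevation field); z is read from it.
#' @param exclude_inner Drop cells overlapping the inner open interior
#'   (the annular default); `FALSE` meshes the full outer rectangle (a
#'   disc), mainly for diagnostics.
#' @return A [tri_mesh()].
#' @export
build_tri_mesh <- function(roi, surface, fraction, s = NULL,
                           exclude_inner = TRUE) {
  stopifnot(inherits(surface, "thickness_grid"))
  o <- roi$outer
  if (o[2] >= surface$width || o[4] >= surface$height || o[1] < 0L || o[3] < 0L) {
    stop("surface does not cover the ROI", call. = FALSE)
  }
  cuts <- plan_square_grid(roi, fraction, s)
  xc <- cuts$x_cuts; yc <- cuts$y_cuts
  nx <- length(xc) - 1L; ny <- length(yc) - 1L
  i <- roi$inner
  # cell (a, b) spans [xc[a], xc[a+1]] x [yc[b], yc[b+1]]
  cell <- expand.grid(a = seq_len(nx), b = seq_len(ny))
  xa <- xc[cell$a]; xb <- xc[cell$a + 1L]
  ya <- yc[cell$b]; yb <- yc[cell$b + 1L]
  overlaps_hole <- xb > i[1] & xa < i[2] & yb > i[3] & ya < i[4]
  if (!exclude_inner) overlaps_hole[] <- FALSE
  keep <- which(!overlaps_hole)
  if (!length(keep)) stop("no mesh cells retained", call. = FALSE)

  # vertices: corners of retained cells, on the (nx+1) x (ny+1) cut lattice
  corner_id <- function(a, b) (b - 1L) * (length(xc)) + a  # cut-lattice index
  ka <- cell$a[keep]; kb <- cell$b[keep]
  cid <- cbind(corner_id(ka, kb),        corner_id(ka + 1L, kb),
               corner_id(ka + 1L, kb + 1L), corner_id(ka, kb + 1L))
  used <- sort(unique(as.vector(cid)))
  remap <- integer(length(xc) * length(yc))
  remap[used] <- seq_along(used)
  vx <- xc[((used - 1L) %% length(xc)) + 1L]
  vy <- yc[((used - 1L) %/% length(xc)) + 1L]
  vz <- grid_value_at(surface, vx, vy)
  # faces: main diagonal ll -> ur, counter-clockwise in the lattice plane
  ll <- remap[cid[, 1L]]; lr <- remap[cid[, 2L]]
  ur <- remap[cid[, 3L]]; ul <- remap[cid[, 4L]]
  faces <- rbind(cbind(ll, lr, ur), cbind(ll, ur, ul))
  tri_mesh(cbind(vx, vy, vz), faces, cbind(vx, vy), surface$pixel_pitch)
}

#' Assemble a subject's functional shape on a shared mesh template
#'
#' Builds the subject's F-shape on the connectivity of `mesh_template`: each
#' vertex keeps the template's lattice point and face structure, its z
#' coordinate is replaced by the subject's ILM elevation there, and the
#' signal is the subject's GCIPL thickness at the same lattice point. All
#' subjects assembled from one template therefore share faces and lattice
#' indices exactly.
#'
#' @param rec A [subject_record()] (right-eye orientation).
#' @param mesh_template A [tri_mesh()] whose lattice indices lie inside the
#'   record's grids.
#' @return An [fshape()].
#' @export
assemble_fshape <- function(rec, mesh_template) {
  stopifnot(inherits(rec, "subject_record"), inherits(mesh_template, "tri_mesh"))
  lx <- mesh_template$lattice[, 1L]; ly <- mesh_template$lattice[, 2L]
  g <- rec$thickness
  if (any(lx < 0L | lx >= g$width | ly < 0L | ly >= g$height)) {
    stop("mesh lattice index out of the subject's grid", call. = FALSE)
  }
  z <- grid_value_at(rec$ilm, lx, ly)
  sig <- grid_value_at(rec$thickness, lx, ly)
  bad <- which(!is.finite(sig) | !is.finite(z))
  if (length(bad)) {
    stop(sprintf("non-finite value at lattice point (%d, %d)",
                 lx[bad[1L]], ly[bad[1L]]), call. = FALSE)
  }
  mesh <- mesh_template
  mesh$vertices <- cbind(lx, ly, z)
  fshape(mesh, sig)
}

#' Euler characteristic of a mesh (V - E + F)
#'
#' 1 for a triangulated disc, 0 for an annulus.
#' @param mesh A [tri_mesh()].
#' @return Integer Euler characteristic.
#' @export
mesh_euler <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])))
  nrow(mesh$vertices) - nrow(edges) + nrow(f)
}

#' Convert an fshape to physical units (mm)
#'
#' x and y move from lattice units to mm via the pixel pitch; z from
#' micrometres to mm. Registration kernels assume these commensurate
#' coordinates.
#' @param fs An [fshape()].
#' @return An [fshape()] with vertices in mm.
#' @export
fshape_to_mm <- function(fs) {
  m <- fs$mesh
  v <- cbind(m$vertices[, 1L] * m$pixel_pitch,
             m$vertices[, 2L] * m$pixel_pitch,
             m$vertices[, 3L] / 1000)
  m$vertices <- v
  fshape(m, fs$signal)
}
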