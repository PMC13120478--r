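#' Export a functional shape as ASCII PLY
#'
#' Writes vertices (x, y, z) with the signal as an extra per-vertex property
#' `signal`, plus the triangular faces.
#'
#' @param fs An [fshape()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(fs, path) {
  stopifnot(inherits(fs, "fshape"))
  v <- fs$mesh$vertices; f <- fs$mesh$faces
  header <- c(
    "ply", "format ascii 1.0",
    "comment macfshape functional shape",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    "property double signal",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  vlines <- sprintf("%.10g %.10g %.10g %.10g", v[, 1], v[, 2], v[, 3], fs$signal)
  flines <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

#' Export a functional shape as legacy ASCII VTK
#'
#' PolyData with one scalar point-data channel carrying the signal.
#'
#' @inheritParams write_ply
#' @return `path`, invisibly.
#' @export
write_vtk <- function(fs, path) {
  stopifnot(inherits(fs, "fshape"))
  v <- fs$mesh$vertices; f <- fs$mesh$faces
  lines <- c(
    "# vtk DataFile Version 3.0",
    "macfshape functional shape",
    "ASCII",
    "DATASET POLYDATA",
    sprintf("POINTS %d double", nrow(v)),
    sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]),
    sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)),
    sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
    sprintf("POINT_DATA %d", nrow(v)),
    "SCALARS signal double 1",
    "LOOKUP_TABLE default",
    sprintf("%.10g", fs$signal)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read back a PLY file written by [write_ply()]
#'
#' @param path PLY file path.
#' @param pixel_pitch Pitch to attach to the mesh (mm per lattice unit).
#' @return An [fshape()] (lattice indices recovered from rounded x, y).
#' @export
read_ply <- function(path, pixel_pitch = 1) {
  lines <- readLines(path)
  endh <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  vdat <- do.call(rbind, lapply(strsplit(lines[endh + seq_len(nv)], " "), as.numeric))
  fdat <- do.call(rbind, lapply(strsplit(lines[endh + nv + seq_len(nf)], " "), as.integer))
  mesh <- tri_mesh(vdat[, 1:3, drop = FALSE], fdat[, 2:4, drop = FALSE] + 1L,
                   cbind(round(vdat[, 1]), round(vdat[, 2])), pixel_pitch)
  fshape(mesh, vdat[, 4])
}
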