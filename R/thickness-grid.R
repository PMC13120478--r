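#' Thickness grid
#'
#' A `thickness_grid` is a 2D scalar field on a regular pixel lattice: either
#' a retinal layer thickness map (micrometres per pixel) or an inner limiting
#' membrane (ILM) elevation field. Values are stored as a numeric matrix with
#' one row per lattice y coordinate and one column per lattice x coordinate;
#' lattice coordinates are 0-based, so the value at lattice point `(x, y)` is
#' `values[y + 1, x + 1]`.
#'
#' @param values Numeric matrix, `height x width`. For thickness layers all
#'   entries must be finite and non-negative.
#' @param pixel_pitch Lattice spacing in mm per pixel (isotropic). Defaults to
#'   a 6 mm scan width divided by the grid width.
#' @param eye_side `"right"` or `"left"`.
#' @param layer_tag Free-text layer label, e.g. `"GCIPL"` or `"ILM_elevation"`.
#'
#' @return An object of class `thickness_grid` with fields `values`, `width`,
#'   `height`, `pixel_pitch`, `eye_side`, `layer_tag`.
#' @export
thickness_grid <- function(values, pixel_pitch = NULL, eye_side = "right",
                           layer_tag = "GCIPL") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("thickness_grid needs positive width and height", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("thickness_grid values must all be finite", call. = FALSE)
  }
  is_thickness <- !grepl("elevation|ILM", layer_tag, ignore.case = TRUE)
  if (is_thickness && any(values < 0)) {
    stop("thickness values must be >= 0", call. = FALSE)
  }
  eye_side <- match.arg(eye_side, c("right", "left"))
  if (is.null(pixel_pitch)) pixel_pitch <- 6 / ncol(values)
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L || pixel_pitch <= 0) {
    stop("pixel_pitch must be a single positive number (mm)", call. = FALSE)
  }
  structure(
    list(
      values = values,
      width = ncol(values),
      height = nrow(values),
      pixel_pitch = pixel_pitch,
      eye_side = eye_side,
      layer_tag = layer_tag
    ),
    class = "thickness_grid"
  )
}

#' @export
print.thickness_grid <- function(x, ...) {
  cat(sprintf(
    "<thickness_grid> %s, %d x %d px @ %.4g mm/px, %s eye\n  values: [%.1f, %.1f], mean %.2f\n",
    x$layer_tag, x$width, x$height, x$pixel_pitch, x$eye_side,
    min(x$values), max(x$values), mean(x$values)
  ))
  invisible(x)
}

#' Value at a 0-based lattice point
#' @param grid A [thickness_grid()].
#' @param x,y 0-based lattice coordinates (vectors allowed).
#' @return Numeric vector of values.
#' @export
grid_value_at <- function(grid, x, y) {
  if (any(x < 0L | x >= grid$width | y < 0L | y >= grid$height)) {
    stop("lattice index out of grid", call. = FALSE)
  }
  grid$values[cbind(y + 1L, x + 1L)]
}

#' Read a thickness grid from disk
#'
#' Two on-disk forms are supported: `delimited_text`, a plain comma-separated
#' file with one grid row per line and `.` as decimal mark, and
#' `binary_container`, the package's documented binary layout (little-endian:
#' the 8-byte magic `"MFSGRID1"`, two int32 `height`, `width`, one float64
#' `pixel_pitch`, one int32 eye-side code 0 = right / 1 = left, then
#' `height * width` float64 values in row-major order). The binary container
#' round-trips bit-exactly.
#'
#' @param path File path.
#' @param format `"delimited_text"` or `"binary_container"`.
#' @param layer_tag Layer label to attach.
#' @return A [thickness_grid()].
#' @export
read_grid <- function(path, format = c("delimited_text", "binary_container"),
                      layer_tag = "GCIPL") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "delimited_text") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    cells <- strsplit(lines, ",", fixed = TRUE)
    lens <- lengths(cells)
    if (length(unique(lens)) != 1L) {
      stop(sprintf(
        "ragged grid file '%s': row lengths %s", path,
        paste(unique(lens), collapse = "/")
      ), call. = FALSE)
    }
    vals <- suppressWarnings(lapply(cells, as.numeric))
    for (i in seq_along(vals)) {
      bad <- which(is.na(vals[[i]]) & !is.na(cells[[i]]))
      if (length(bad)) {
        stop(sprintf(
          "non-numeric cell at row %d, column %d of '%s'", i, bad[1L], path
        ), call. = FALSE)
      }
    }
    m <- do.call(rbind, vals)
    thickness_grid(m, layer_tag = layer_tag)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readChar(con, 8L, useBytes = TRUE)
    if (!identical(magic, "MFSGRID1")) {
      stop("not a macfshape binary grid container: ", path, call. = FALSE)
    }
    dims <- readBin(con, "integer", 2L, size = 4L, endian = "little")
    pitch <- readBin(con, "double", 1L, size = 8L, endian = "little")
    side <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    vals <- readBin(con, "double", dims[1L] * dims[2L], size = 8L, endian = "little")
    m <- matrix(vals, nrow = dims[1L], ncol = dims[2L], byrow = TRUE)
    thickness_grid(m, pixel_pitch = pitch,
                   eye_side = if (side == 1L) "left" else "right",
                   layer_tag = layer_tag)
  }
}

#' Write a thickness grid to disk
#'
#' @inheritParams read_grid
#' @param grid A [thickness_grid()].
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, format = c("delimited_text", "binary_container")) {
  format <- match.arg(format)
  stopifnot(inherits(grid, "thickness_grid"))
  if (format == "delimited_text") {
    lines <- apply(grid$values, 1L, function(r) {
      paste(format(r, scientific = FALSE, trim = TRUE, digits = 15), collapse = ",")
    })
    writeLines(lines, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar("MFSGRID1", con, nchars = 8L, eos = NULL)
    writeBin(c(grid$height, grid$width), con, size = 4L, endian = "little")
    writeBin(grid$pixel_pitch, con, size = 8L, endian = "little")
    writeBin(if (grid$eye_side == "left") 1L else 0L, con, size = 4L, endian = "little")
    writeBin(as.vector(t(grid$values)), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a thickness grid
#'
#' @param object A [thickness_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot thickness_grid
#' @export
autoplot.thickness_grid <- function(object, ...) {
  df <- tibble::tibble(
    x = rep(seq_len(object$width) - 1L, each = object$height),
    y = rep(seq_len(object$height) - 1L, times = object$width),
    value = as.vector(object$values)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$layer_tag) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}
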