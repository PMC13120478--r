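#' Per-eye subject record
#'
#' Bundles the GCIPL thickness map and the ILM elevation field of one eye
#' with its identifiers and class label. Both grids must share the same
#' lattice dimensions and pixel pitch.
#'
#' @param subject_id,eye_id Identifier strings.
#' @param label `"healthy"` or `"MS"`.
#' @param thickness GCIPL [thickness_grid()].
#' @param ilm ILM elevation [thickness_grid()] (micrometres of elevation).
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, eye_id, label, thickness, ilm) {
  label <- match.arg(label, c("healthy", "MS"))
  stopifnot(inherits(thickness, "thickness_grid"), inherits(ilm, "thickness_grid"))
  if (thickness$width != ilm$width || thickness$height != ilm$height ||
      !isTRUE(all.equal(thickness$pixel_pitch, ilm$pixel_pitch))) {
    stop("thickness and ILM grids must share lattice dimensions and pixel pitch",
         call. = FALSE)
  }
  if (thickness$eye_side != ilm$eye_side) {
    stop("thickness and ILM grids disagree on eye side", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, eye_id = eye_id, label = label,
         thickness = thickness, ilm = ilm),
    class = "subject_record"
  )
}

mirror_grid <- function(grid) {
  flipped <- grid$values[, rev(seq_len(grid$width)), drop = FALSE]
  thickness_grid(flipped, pixel_pitch = grid$pixel_pitch,
                 eye_side = grid$eye_side, layer_tag = grid$layer_tag)
}

#' Normalize eye orientation to the right-eye convention
#'
#' Left-eye grids are mirrored about the vertical midline
#' (`x -> width - 1 - x`), which swaps the nasal and temporal sides, and the
#' record is relabelled as right-convention. Right-eye records pass through
#' unchanged. Applying the flip twice restores the original values.
#'
#' @param rec A [subject_record()].
#' @return A [subject_record()] in right-eye orientation.
#' @export
normalize_orientation <- function(rec) {
  stopifnot(inherits(rec, "subject_record"))
  if (rec$thickness$eye_side == "right") return(rec)
  th <- mirror_grid(rec$thickness); th$eye_side <- "right"
  il <- mirror_grid(rec$ilm); il$eye_side <- "right"
  subject_record(rec$subject_id, rec$eye_id, rec$label, th, il)
}

#' Read / write a cohort manifest
#'
#' A manifest is one CSV with columns `subject_id`, `eye_id`, `label`,
#' `side`, `thickness_path`, `ilm_path`; paths are relative to the manifest's
#' directory.
#'
#' @param path Manifest CSV path.
#' @return `read_manifest`: a tibble with one row per eye.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "eye_id", "label", "side", "thickness_path", "ilm_path")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("manifest missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_manifest
#' @param manifest Tibble of manifest rows.
#' @return `write_manifest`: `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load the subject records listed in a manifest
#'
#' @param path Manifest CSV path.
#' @param format Grid file format, as in [read_grid()].
#' @return List of [subject_record()] objects.
#' @export
load_cohort <- function(path, format = "binary_container") {
  man <- read_manifest(path)
  base <- dirname(path)
  purrr::pmap(man, function(subject_id, eye_id, label, side,
                            thickness_path, ilm_path, ...) {
    th <- read_grid(file.path(base, thickness_path), format, layer_tag = "GCIPL")
    il <- read_grid(file.path(base, ilm_path), format, layer_tag = "ILM_elevation")
    th$eye_side <- side; il$eye_side <- side
    subject_record(subject_id, eye_id, label, th, il)
  })
}
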