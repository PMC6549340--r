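# Image-set bookkeeping: filename-convention parsing, per-well grouping, and
# frame loading for TIFF/PNG grayscale frames.

#' Read one grayscale frame from disk
#'
#' @param path A `.tif`/`.tiff` or `.png` file.
#' @return Numeric intensity matrix on the `[0, 1]` scale.
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    rlang::abort(sprintf("unsupported image format: %s", path))
  )
  if (length(dim(img)) == 3) img <- img[, , 1] # first channel of RGB(A)
  img
}

#' Index an image directory into a per-well frame manifest
#'
#' Files must follow the `{plate}_{well}_{frame}.{tif,tiff,png}` convention
#' (frame indices may be zero-padded). Frames are grouped per plate and well
#' and sorted by frame index, so a shuffled directory listing yields the same
#' manifest. Unparseable filenames are skipped and reported via the
#' `"skipped"` attribute; wells with gaps in their frame sequence are listed
#' in the `"missing"` attribute.
#'
#' @param dir Directory of frames.
#' @return Tibble (`plate`, `well`, `frame`, `path`), sorted; attributes
#'   `"skipped"` (character) and `"missing"` (tibble of well/frame gaps).
#' @export
read_image_set <- function(dir) {
  files <- list.files(dir, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE)
  m <- regmatches(files, regexec("^(.+)_([A-P][0-9]{2})_([0-9]+)\\.(tif|tiff|png)$",
                                 files, ignore.case = TRUE))
  ok <- vapply(m, length, integer(1)) == 5L
  skipped <- files[!ok]
  if (length(skipped)) {
    rlang::warn(sprintf("%d file(s) did not match the {plate}_{well}_{frame} convention and were skipped",
                        length(skipped)))
  }
  manifest <- tibble::tibble(
    plate = vapply(m[ok], `[`, "", 2L),
    well = toupper(vapply(m[ok], `[`, "", 3L)),
    frame = as.integer(vapply(m[ok], `[`, "", 4L)),
    path = file.path(dir, files[ok])
  ) |>
    dplyr::arrange(.data$plate, .data$well, .data$frame)
  if (nrow(manifest) == 0) rlang::warn("no frames found")
  missing <- if (nrow(manifest) == 0) {
    tibble::tibble(plate = character(0), well = character(0), frame = integer(0))
  } else {
    manifest |>
      dplyr::group_by(.data$plate, .data$well) |>
      dplyr::reframe(frame = setdiff(seq(min(.data$frame), max(.data$frame)), .data$frame))
  }
  attr(manifest, "skipped") <- skipped
  attr(manifest, "missing") <- missing
  manifest
}

#' Load the frames of one well from a manifest
#'
#' @param manifest A [read_image_set()] manifest.
#' @param plate,well Plate and well to load.
#' @return Time-ordered list of frame matrices.
#' @export
load_well_frames <- function(manifest, plate, well) {
  rows <- manifest[manifest$plate == plate & manifest$well == well, ]
  if (nrow(rows) == 0) rlang::abort(sprintf("no frames for %s %s", plate, well))
  purrr::map(rows$path[order(rows$frame)], read_frame)
}
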