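# Shared helpers: well coordinates, seeds, input checks.

PLATE_ROWS <- 16L
PLATE_COLS <- 24L

#' Well names for a 384-well plate
#'
#' Wells are labelled by letter row (A-P) and 1-based column (1-24),
#' zero-padded in files (`A01` ... `P24`), in row-major order.
#'
#' @param rows,cols Integer row (1-16) and column (1-24) indices, recycled.
#' @return Character vector of well labels.
#' @export
#' @examples
#' well_name(1, 7)
well_name <- function(rows, cols) {
  stopifnot(all(rows >= 1 & rows <= PLATE_ROWS), all(cols >= 1 & cols <= PLATE_COLS))
  sprintf("%s%02d", LETTERS[rows], as.integer(cols))
}

#' @rdname well_name
#' @param well Character vector of well labels such as `"B07"`.
#' @return `parse_well()` returns a tibble with columns `well`, `row`, `col`.
#' @export
parse_well <- function(well) {
  m <- regmatches(well, regexec("^([A-P])0*([0-9]{1,2})$", well))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    rlang::abort(paste0("unparseable well label(s): ", paste(well[bad], collapse = ", ")))
  }
  row <- match(vapply(m, `[`, "", 2L), LETTERS)
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(col < 1 | col > PLATE_COLS)) rlang::abort("well column out of 1-24 range")
  tibble::tibble(well = well, row = row, col = col)
}

# All 384 well labels in row-major order.
all_wells <- function(n_wells = 384L) {
  idx <- seq_len(n_wells) - 1L
  well_name(idx %/% PLATE_COLS + 1L, idx %% PLATE_COLS + 1L)
}

# Derive a bounded child seed from a master seed and a stream id.
derive_seed <- function(seed, stream) {
  (as.integer(seed) + as.integer(stream)) %% .Machine$integer.max
}

check_frame <- function(frame, arg = "frame") {
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0) {
    rlang::abort(sprintf("`%s` must be a non-empty numeric matrix", arg))
  }
  if (!all(is.finite(frame))) {
    rlang::abort(sprintf("`%s` contains non-finite intensities", arg))
  }
  invisible(frame)
}

# L1 norm.
l1 <- function(x) sum(abs(x))
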