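# Label-free quantification of per-well phase-contrast time series:
# adaptive background segmentation, confluence change over time, and
# hierarchical-pixel-histogram (PHHC) morphology change over time.
#
# Frames are plain numeric matrices of grayscale intensities; a well is an
# ordered list of frames sharing dimensions. All per-frame computations are
# independent (map step); per-well vectors are assembled afterwards (reduce
# step), so processing order never affects results.

#' Global background intensity estimate of a frame
#'
#' Background dominates phase-contrast frames of adherent cultures, so the
#' median intensity is a robust estimate of the background level.
#'
#' @param frame Numeric intensity matrix.
#' @return Scalar background intensity.
#' @export
estimate_background_level <- function(frame) {
  check_frame(frame)
  stats::median(frame)
}

otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(EBImage::Image(matrix(x, nrow = 1)), range = rng, levels = 256L)
}

#' Adaptive background intensity interval
#'
#' Splits a frame's intensities at the global background estimate and
#' applies Otsu's method independently to each side: the sub-median
#' population yields the lower bound `lo` (separating dark foreground from
#' background), the supra-median population the upper bound `hi` (separating
#' bright halos from background). Pixels inside `[lo, hi]` are background.
#'
#' @param frame Numeric intensity matrix.
#' @return A `background_interval`: list with `lo`, `hi`, `mu_b`.
#' @export
adaptive_background_interval <- function(frame) {
  check_frame(frame)
  mu <- stats::median(frame)
  lower <- frame[frame < mu]
  upper <- frame[frame > mu]
  if (length(unique(as.vector(frame))) == 1L) {
    rlang::warn("constant frame: degenerate background interval")
    return(structure(list(lo = mu, hi = mu, mu_b = mu), class = "background_interval"))
  }
  # a side with fewer than 2 distinct values cannot be split: treat it as
  # all-background by extending the interval to the frame extreme
  lo <- if (length(unique(lower)) >= 2) otsu_threshold(lower) else min(frame)
  hi <- if (length(unique(upper)) >= 2) otsu_threshold(upper) else max(frame)
  structure(list(lo = min(lo, mu), hi = max(hi, mu), mu_b = mu),
            class = "background_interval")
}

#' @export
print.background_interval <- function(x, ...) {
  cat(sprintf("<background_interval> [%g, %g], mu_b = %g\n", x$lo, x$hi, x$mu_b))
  invisible(x)
}

#' Foreground mask of a frame
#'
#' @param frame Numeric intensity matrix.
#' @param interval A [adaptive_background_interval()].
#' @return Logical matrix, `TRUE` where intensity falls outside
#'   `[interval$lo, interval$hi]` (foreground).
#' @export
segment_foreground <- function(frame, interval) {
  check_frame(frame)
  if (!inherits(interval, "background_interval")) {
    rlang::abort("`interval` must be a background_interval")
  }
  frame < interval$lo | frame > interval$hi
}

#' Confluence of a foreground mask
#'
#' @param mask Logical matrix from [segment_foreground()].
#' @return Foreground pixel fraction in `[0, 1]`.
#' @export
confluence <- function(mask) {
  if (length(mask) == 0 || !is.logical(mask)) rlang::abort("`mask` must be a non-empty logical array")
  mean(mask)
}

#' Relative confluence change over time
#'
#' `delta_confluence(c)[i] = (c[i] - c[1]) / c[1]`: the growth curve of a
#' well relative to its first recorded frame (0 at the first time point,
#' negative when confluence shrinks).
#'
#' @param series Numeric vector of per-frame confluence values, time-ordered.
#' @param well Optional well label used in error messages.
#' @return Numeric vector, first element 0.
#' @export
delta_confluence <- function(series, well = NULL) {
  if (length(series) == 0) rlang::abort("empty confluence series")
  if (series[1] == 0) {
    rlang::abort(sprintf("zero confluence at the reference frame%s",
                         if (is.null(well)) "" else paste0(" of well ", well)))
  }
  (series - series[1]) / series[1]
}

#' Hierarchical pixel histogram (PHHC) morphology features
#'
#' Builds a multi-resolution pyramid of the frame (antialiased local
#' averaging, factor `scale_reduction` per level; masks are downsampled
#' nearest-neighbor) and, at each level, histograms the foreground pixel
#' intensities into `n_bins` fixed-range bins. Level histograms are
#' concatenated into one feature vector of length `n_levels * n_bins`.
#' A fixed `bin_range` shared across wells makes vectors comparable
#' plate-wide.
#'
#' @param frame Numeric intensity matrix.
#' @param mask Logical foreground mask of the same shape.
#' @param n_levels Pyramid depth (default 3).
#' @param n_bins Histogram bins per level (default 16).
#' @param scale_reduction Linear downsampling factor per level (default 2).
#' @param bin_range Length-2 intensity range of the bins; defaults to the
#'   frame's own range (pass a plate-wide range for comparable features).
#' @return Numeric vector of length `n_levels * n_bins` (class `phhc`).
#' @export
phhc_features <- function(frame, mask, n_levels = 3L, n_bins = 16L,
                          scale_reduction = 2, bin_range = NULL) {
  check_frame(frame)
  if (!is.logical(mask) || !identical(dim(mask), dim(frame))) {
    rlang::abort("`mask` must be a logical matrix matching `frame`")
  }
  if (n_levels < 1 || n_bins < 2 || scale_reduction <= 1) {
    rlang::abort("need n_levels >= 1, n_bins >= 2, scale_reduction > 1")
  }
  if (is.null(bin_range)) bin_range <- range(frame)
  if (diff(bin_range) == 0) bin_range <- bin_range + c(-0.5, 0.5)
  h <- numeric(0)
  f <- frame
  m <- mask
  for (lev in seq_len(n_levels)) {
    vals <- f[m]
    # clamp out-of-range intensities into the edge bins
    idx <- findInterval(pmin(pmax(vals, bin_range[1]), bin_range[2]),
                        seq(bin_range[1], bin_range[2], length.out = n_bins + 1),
                        rightmost.closed = TRUE, all.inside = TRUE)
    h <- c(h, tabulate(idx, nbins = n_bins))
    if (lev < n_levels) {
      nd <- pmax(1L, round(dim(f) / scale_reduction))
      f <- as.matrix(EBImage::resize(EBImage::Image(f), w = nd[1], h = nd[2],
                                     antialias = TRUE))
      m <- as.matrix(EBImage::resize(EBImage::Image(m * 1), w = nd[1], h = nd[2],
                                     filter = "none")) > 0.5
    }
  }
  if (sum(h) == 0) rlang::warn("empty foreground at every pyramid level: zero PHHC vector")
  structure(h, class = c("phhc", "numeric"),
            params = list(n_levels = n_levels, n_bins = n_bins,
                          scale_reduction = scale_reduction, bin_range = bin_range))
}

#' Relative morphology change over time
#'
#' `delta_morphology(H)[i] = ||h_i - h_1||_1 / ||h_1||_1`: L1 distance of
#' each frame's PHHC vector to the first frame's, normalized by the first
#' frame's L1 mass. Zero at the first time point, non-negative after; the
#' normalization compensates for seeding-density differences between wells.
#'
#' @param features List of PHHC vectors (time-ordered), or a matrix with one
#'   row per time point.
#' @param well Optional well label for error messages.
#' @return Non-negative numeric vector, first element 0.
#' @export
delta_morphology <- function(features, well = NULL) {
  if (is.matrix(features)) features <- asplit(features, 1)
  if (length(features) == 0) rlang::abort("empty feature series")
  h0 <- as.numeric(features[[1]])
  n0 <- l1(h0)
  if (n0 == 0) {
    rlang::abort(sprintf("zero-norm reference histogram%s",
                         if (is.null(well)) "" else paste0(" in well ", well)))
  }
  vapply(features, function(h) l1(as.numeric(h) - h0) / n0, numeric(1))
}

#' Quantify one well's frame series
#'
#' Runs segmentation, confluence, and PHHC morphology on each frame of a
#' well and assembles the temporal profile. Frames are processed
#' independently, so any processing order yields the same profile.
#'
#' @param frames List of numeric matrices, time-ordered.
#' @param times_h Numeric vector of acquisition times in hours.
#' @param well Well label.
#' @param bin_range Plate-wide histogram range (see [phhc_features()]).
#' @param ... PHHC parameters passed to [phhc_features()].
#' @return Tibble with columns `well`, `time_h`, `confluence`,
#'   `delta_confluence`, `delta_morphology`; the per-frame PHHC matrix is
#'   attached as attribute `"phhc"`.
#' @export
well_features <- function(frames, times_h = seq_along(frames), well = "w",
                          bin_range = NULL, ...) {
  if (length(frames) == 0) rlang::abort("well has no frames")
  dims <- unique(purrr::map(frames, dim))
  if (length(dims) != 1) rlang::abort(sprintf("inconsistent frame sizes in well %s", well))
  per_frame <- purrr::map(frames, function(f) {
    iv <- suppressWarnings(adaptive_background_interval(f))
    mask <- segment_foreground(f, iv)
    list(conf = confluence(mask),
         h = suppressWarnings(phhc_features(f, mask, bin_range = bin_range, ...)))
  })
  conf <- purrr::map_dbl(per_frame, "conf")
  H <- do.call(rbind, purrr::map(per_frame, function(x) as.numeric(x$h)))
  out <- tibble::tibble(
    well = well, time_h = times_h, confluence = conf,
    delta_confluence = delta_confluence(conf, well = well),
    delta_morphology = delta_morphology(H, well = well)
  )
  attr(out, "phhc") <- H
  out
}

#' Quantify a whole plate of wells
#'
#' Fixes the PHHC histogram range from the global intensity range of every
#' well's first frame (so morphology vectors are comparable across wells),
#' then runs [well_features()] per well.
#'
#' @param well_frames Named list: one list of time-ordered frames per well.
#' @param times_h Acquisition times in hours (shared across wells).
#' @param ... PHHC parameters passed on to [phhc_features()].
#' @return Tibble of row-bound per-well profiles; attribute `"phhc_t0"`
#'   holds the matrix of first-frame PHHC vectors (one row per well) used by
#'   intra-plate QC, and attribute `"bin_range"` the shared histogram range.
#' @export
plate_features <- function(well_frames, times_h = NULL, ...) {
  if (length(well_frames) == 0) rlang::abort("no wells supplied")
  if (is.null(names(well_frames))) rlang::abort("`well_frames` must be named by well")
  bin_range <- range(purrr::map(well_frames, function(fr) range(fr[[1]])))
  profiles <- purrr::imap(well_frames, function(frames, w) {
    well_features(frames, times_h = times_h %||% seq_along(frames),
                  well = w, bin_range = bin_range, ...)
  })
  out <- purrr::list_rbind(purrr::map(profiles, function(p) {
    p2 <- p
    attr(p2, "phhc") <- NULL
    p2
  }))
  t0 <- do.call(rbind, purrr::map(profiles, function(p) attr(p, "phhc")[1, ]))
  rownames(t0) <- names(well_frames)
  attr(out, "phhc_t0") <- t0
  attr(out, "bin_range") <- bin_range
  out
}
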