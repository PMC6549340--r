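# Matched-filter detection and counting of prototype-like objects
# (apoptotic-like cells) with cross-validated threshold tuning.
#
# The detector is a linear matched filter: for a user-selected prototype
# patch s and scalar background level b, the coefficient patch is w = s - b
# (white-noise covariance), and the response at each fully-contained patch
# position is the dot product of w with the local patch. Objects are counted
# on the thresholded response by two independent algorithms (greedy taboo
# peak-picking and interval-projection position counting) whose mean is the
# per-frame count.

#' Build a matched filter from a prototype patch
#'
#' @param prototype Numeric matrix: a small image patch containing one
#'   prototypical object (both dimensions at least 3).
#' @param background_level Scalar background intensity `b`, broadcast over
#'   the patch; the filter coefficients are `w = prototype - b`.
#' @return A `matched_filter` object: list with `s`, `b`, `w`, `tau` (`NULL`
#'   until tuned or set), and `tuning` (report tibble after
#'   [tune_threshold()]).
#' @export
build_filter <- function(prototype, background_level) {
  check_frame(prototype, "prototype")
  if (any(dim(prototype) < 3)) rlang::abort("prototype must be at least 3x3")
  if (length(background_level) != 1 || !is.finite(background_level)) {
    rlang::abort("`background_level` must be a finite scalar")
  }
  w <- prototype - background_level
  if (all(w == 0)) rlang::warn("degenerate filter: prototype equals background everywhere")
  structure(list(s = prototype, b = background_level, w = w, tau = NULL, tuning = NULL),
            class = "matched_filter")
}

#' @export
print.matched_filter <- function(x, ...) {
  cat(sprintf("<matched_filter> %dx%d patch, b = %g, tau = %s\n",
              nrow(x$w), ncol(x$w), x$b,
              if (is.null(x$tau)) "untuned" else format(x$tau)))
  invisible(x)
}

#' Set the detection threshold of a filter explicitly
#'
#' @param model A [build_filter()] model.
#' @param tau Finite scalar threshold in response units.
#' @return The model with `tau` set.
#' @export
set_threshold <- function(model, tau) {
  if (length(tau) != 1 || !is.finite(tau)) rlang::abort("`tau` must be a finite scalar")
  model$tau <- tau
  model
}

#' Matched filter response map
#'
#' Computes the sliding dot product of the coefficient patch with every
#' fully-contained position of the frame ("valid" correlation, no padding):
#' for an H x W frame and an Nr x Nc patch the response has shape
#' (H - Nr + 1, W - Nc + 1), entry (i, j) being
#' `sum(w * frame[i:(i+Nr-1), j:(j+Nc-1)])`.
#'
#' @param frame Numeric intensity matrix at least as large as the patch.
#' @param model A [build_filter()] model.
#' @return Numeric response matrix (class `response_map`), with the patch
#'   shape attached as attribute `"patch_shape"`.
#' @export
filter_response <- function(frame, model) {
  check_frame(frame)
  w <- model$w
  if (nrow(frame) < nrow(w) || ncol(frame) < ncol(w)) {
    rlang::abort("frame smaller than the filter patch")
  }
  nr <- nrow(frame) - nrow(w) + 1L
  nc <- ncol(frame) - ncol(w) + 1L
  y <- matrix(0, nr, nc)
  # shifted-sum correlation: one vectorized update per patch coefficient
  for (u in seq_len(nrow(w))) {
    for (v in seq_len(ncol(w))) {
      if (w[u, v] != 0) {
        y <- y + w[u, v] * frame[u:(u + nr - 1L), v:(v + nc - 1L), drop = FALSE]
      }
    }
  }
  structure(y, class = c("response_map", "matrix", "array"),
            patch_shape = dim(w))
}

# Center offsets of a patch dimension: for odd n the true center, for even n
# rounded toward the top-left ((lo, hi) extents around the center index).
center_extent <- function(n) c(ceiling((n - 1) / 2), floor((n - 1) / 2))

#' Taboo-based object counting
#'
#' Greedy peak picking on the response map: repeatedly take the largest
#' non-tabooed response; stop when it falls below `tau`, otherwise accept a
#' detection there and taboo the patch-shaped neighborhood centered on it.
#' Accepted centers are therefore separated by at least the patch extent on
#' at least one axis.
#'
#' @param resp A [filter_response()] map.
#' @param tau Finite detection threshold (response units).
#' @param patch_shape Integer (rows, cols) of the filter patch; defaults to
#'   the shape recorded on the response map.
#' @return List with `count` and `centers` (two-column matrix of response-map
#'   row/col positions of accepted peaks).
#' @export
taboo_count <- function(resp, tau, patch_shape = attr(resp, "patch_shape")) {
  if (!is.finite(tau)) rlang::abort("`tau` must be finite")
  if (is.null(patch_shape)) rlang::abort("`patch_shape` required")
  work <- unclass(resp)
  re <- center_extent(patch_shape[1])
  ce <- center_extent(patch_shape[2])
  centers <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col")))
  repeat {
    i <- which.max(work)
    if (length(i) == 0 || work[i] < tau) break
    pos <- arrayInd(i, dim(work))
    centers <- rbind(centers, pos)
    rows <- max(1L, pos[1] - re[1]):min(nrow(work), pos[1] + re[2])
    cols <- max(1L, pos[2] - ce[1]):min(ncol(work), pos[2] + ce[2])
    work[rows, cols] <- -Inf
  }
  list(count = nrow(centers), centers = centers)
}

# Maximal runs of TRUE in a logical vector -> two-column matrix (start, end).
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Position-based object counting
#'
#' Interval projection on the thresholded response (`resp >= tau`): first
#' find maximal contiguous column intervals containing any supra-threshold
#' pixel (horizontal pass); within each such interval find maximal contiguous
#' row intervals of supra-threshold pixels (vertical pass); the total count
#' is the sum over horizontal intervals of their vertical-interval counts.
#'
#' @inheritParams taboo_count
#' @return Integer object count.
#' @export
position_count <- function(resp, tau) {
  if (!is.finite(tau)) rlang::abort("`tau` must be finite")
  b <- unclass(resp) >= tau
  col_hit <- apply(b, 2, any)
  if (!any(col_hit)) return(0L)
  h_intervals <- true_runs(col_hit)
  total <- 0L
  for (k in seq_len(nrow(h_intervals))) {
    sub <- b[, h_intervals[k, 1]:h_intervals[k, 2], drop = FALSE]
    row_hit <- apply(sub, 1, any)
    total <- total + nrow(true_runs(row_hit))
  }
  total
}

#' Count objects in one frame with both algorithms
#'
#' @param frame Numeric intensity matrix.
#' @param model A tuned [build_filter()] model (or one with `tau` set via
#'   [set_threshold()]).
#' @param tau Optional threshold override.
#' @return Tibble row: `taboo`, `position`, `mean_count`, and `centers`
#'   (list column with the taboo detections).
#' @export
frame_count <- function(frame, model, tau = model$tau) {
  if (is.null(tau)) {
    rlang::abort("filter has no detection threshold: tune or set one first",
                 class = "combiscreen_not_tuned")
  }
  resp <- filter_response(frame, model)
  tb <- taboo_count(resp, tau)
  pc <- position_count(resp, tau)
  tibble::tibble(taboo = tb$count, position = pc,
                 mean_count = (tb$count + pc) / 2, centers = list(tb$centers))
}

#' Temporal object counts for one well
#'
#' Runs [frame_count()] on each frame (map) and collects the per-time mean
#' counts in time order (reduce); results are independent of processing
#' order.
#'
#' @param frames Time-ordered list of frames from one well.
#' @param model Tuned [build_filter()] model.
#' @param times_h Optional acquisition times.
#' @param well Well label.
#' @return Tibble with columns `well`, `time_h`, `taboo`, `position`,
#'   `mean_count`.
#' @export
well_counts <- function(frames, model, times_h = seq_along(frames), well = "w") {
  if (length(frames) == 0) rlang::abort("well has no frames")
  dims <- unique(purrr::map(frames, dim))
  if (length(dims) != 1) rlang::abort("inconsistent frame sizes within a well")
  counts <- purrr::map(frames, frame_count, model = model)
  dplyr::bind_cols(tibble::tibble(well = well, time_h = times_h),
                   dplyr::select(purrr::list_rbind(counts), -"centers"))
}

# Mean absolute count error of threshold tau over precomputed responses.
tuning_loss <- function(tau, resps, observed) {
  pred <- vapply(resps, function(r) {
    (taboo_count(r, tau)$count + position_count(r, tau)) / 2
  }, numeric(1))
  mean(abs(observed - pred))
}

# Interval optimization of the loss over tau: evaluate a spread of starting
# points across the supra-background response range, then refine around the
# best one by golden-section search; ties break toward larger tau (fewer
# detections).
optimize_tau <- function(resps, observed, background_response, n_starts = 11L,
                         refine_iter = 20L) {
  pooled <- unlist(purrr::map(resps, as.vector))
  supra <- pooled[pooled > background_response]
  if (length(supra) < 2) supra <- pooled
  starts <- unique(stats::quantile(supra, probs = seq(0, 1, length.out = n_starts),
                                   names = FALSE))
  losses <- vapply(starts, tuning_loss, numeric(1), resps = resps, observed = observed)
  best <- max(which(losses == min(losses))) # tie -> larger tau
  lo <- if (best > 1) starts[best - 1] else starts[best]
  hi <- if (best < length(starts)) starts[best + 1] else starts[best]
  best_tau <- starts[best]
  best_loss <- losses[best]
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  for (i in seq_len(refine_iter)) {
    if (b - a <= 0) break
    x1 <- b - phi * (b - a)
    x2 <- a + phi * (b - a)
    f1 <- tuning_loss(x1, resps, observed)
    f2 <- tuning_loss(x2, resps, observed)
    if (f2 < best_loss || (f2 == best_loss && x2 > best_tau)) { best_loss <- f2; best_tau <- x2 }
    if (f1 < best_loss || (f1 == best_loss && x1 > best_tau)) { best_loss <- f1; best_tau <- x1 }
    if (f1 < f2) b <- x2 else a <- x1 # tie -> keep the larger-tau bracket
  }
  list(tau = best_tau, loss = best_loss)
}

#' Tune the detection threshold by cross-validated interval search
#'
#' Supervised tuning against manually annotated training frames. For each
#' cross-validation partition the mean absolute difference between observed
#' and predicted counts (predicted = mean of the two counting algorithms) is
#' minimized over the threshold -- first over a set of starting points
#' spanning the pooled supra-background response range, then by interval
#' refinement -- giving a fold optimum `tau_j` and its held-out test loss.
#' If the median test loss exceeds `overfit_cutoff` the tuning aborts
#' (overfitting: annotations and responses are inconsistent; more training
#' data is needed). Otherwise the final threshold is the median of the fold
#' optima.
#'
#' @param training Tibble (or data frame) with a list column `frame` of
#'   training frames and a numeric column `observed` of manually annotated
#'   object counts; at least `folds` rows.
#' @param model A [build_filter()] model.
#' @param folds Cross-validation folds (default 4).
#' @param repeats Number of repeated fold assignments (default 2).
#' @param overfit_cutoff Abort when the median held-out loss exceeds this
#'   count difference (default 5).
#' @param seed Seed for the fold assignments.
#' @return The model with `tau` set and a `tuning` report tibble
#'   (`repeat_id`, `fold`, `tau_j`, `test_loss`).
#' @export
tune_threshold <- function(training, model, folds = 4L, repeats = 2L,
                           overfit_cutoff = 5, seed = 1L) {
  n <- nrow(training)
  if (is.null(n) || n < folds) rlang::abort("need at least `folds` training images")
  resps <- purrr::map(training$frame, filter_response, model = model)
  observed <- training$observed
  bg_resp <- sum(model$w) * model$b
  report <- withr::with_seed(seed, {
    purrr::map(seq_len(repeats), function(rep_id) {
      fold_of <- sample(rep_len(seq_len(folds), n))
      purrr::map(seq_len(folds), function(j) {
        tr <- fold_of != j
        opt <- optimize_tau(resps[tr], observed[tr], bg_resp)
        tibble::tibble(repeat_id = rep_id, fold = j, tau_j = opt$tau,
                       train_loss = opt$loss,
                       test_loss = tuning_loss(opt$tau, resps[!tr], observed[!tr]))
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  if (stats::median(report$test_loss) > overfit_cutoff) {
    rlang::abort(sprintf(
      "threshold tuning aborted: median held-out loss %.2f exceeds %.2f (overfitting); re-train with more annotated images",
      stats::median(report$test_loss), overfit_cutoff),
      class = "combiscreen_overfit", report = report)
  }
  model$tau <- stats::median(report$tau_j)
  model$tuning <- report
  model
}
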