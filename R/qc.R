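# Two-stage assay quality control: intra-plate well exclusion on early-frame
# morphology features, then resampling-based inter-plate outlier rejection of
# conditions whose replicate growth curves disagree too much to merge.

# Relative L1 distance between two histograms, 2 for disjoint equal-mass
# histograms and 0 for identical ones.
rel_l1 <- function(a, b) {
  denom <- (l1(a) + l1(b)) / 2
  if (denom == 0) return(0)
  l1(a - b) / denom
}

#' Intra-plate QC on first-frame morphology features
#'
#' At the earliest (ideally pre-effect) time point all wells should contain
#' untreated-looking cells, so their PHHC feature vectors should be similar.
#' Wells whose median relative L1 distance to all other wells exceeds a
#' robust automatic cutoff (median + 3 MAD of the per-well medians) are
#' flagged and must be excluded from every downstream analysis.
#'
#' @param features_t0 Numeric matrix of first-frame PHHC vectors, one row per
#'   well, rownames = well labels (e.g. attribute `"phhc_t0"` of
#'   [plate_features()]); or a named list of vectors.
#' @param n_mad Cutoff multiplier on the MAD (default 3).
#' @return Tibble with columns `well`, `median_distance`, `pass`.
#' @export
intra_plate_qc <- function(features_t0, n_mad = 3) {
  if (is.list(features_t0)) features_t0 <- do.call(rbind, features_t0)
  n <- nrow(features_t0)
  if (is.null(n) || n < 3) rlang::abort("intra-plate QC needs at least 3 wells")
  wells <- rownames(features_t0) %||% as.character(seq_len(n))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- rel_l1(features_t0[i, ], features_t0[j, ])
    }
  }
  med <- vapply(seq_len(n), function(i) stats::median(d[i, -i]), numeric(1))
  cutoff <- stats::median(med) + n_mad * stats::mad(med)
  tibble::tibble(well = wells, median_distance = med, pass = med <= cutoff)
}

#' Inter-plate variability of one condition
#'
#' The area between the replicate growth curves: at each time point take the
#' span (max minus min) of the replicates' relative confluence change, and
#' sum the spans over time. Zero when replicates agree exactly.
#'
#' @param curves Numeric matrix of growth curves (`delta_confluence`), one
#'   row per replicate plate and one column per time point; or a list of
#'   equal-length vectors.
#' @return Non-negative scalar `V_w`.
#' @export
inter_plate_variability <- function(curves) {
  if (is.list(curves)) {
    if (length(unique(lengths(curves))) != 1) rlang::abort("replicate curves have mismatched time axes")
    curves <- do.call(rbind, curves)
  }
  if (nrow(curves) < 2) rlang::abort("need at least 2 replicates")
  sum(apply(curves, 2, max) - apply(curves, 2, min))
}

#' Resampling null distribution of inter-plate variability
#'
#' Under the null hypothesis that a condition behaves like untreated cells,
#' its inter-plate variability should look like the variability of a random
#' draw of one untreated well per replicate plate. Each of `n_sims`
#' simulations samples one eligible untreated well per plate with
#' replacement, computes [inter_plate_variability()] over the draw, and the
#' stated percentile of the collected values becomes the QC threshold.
#'
#' @param untreated_curves List with one element per replicate plate, each a
#'   matrix of untreated growth curves (rows = wells passing intra-plate QC,
#'   columns = time points).
#' @param n_sims Number of resampling simulations (default 10000).
#' @param percentile Threshold percentile of the null distribution
#'   (default 95, i.e. a 5% false-alarm probability).
#' @param seed Seed for the resampling.
#' @return A `variability_null` object: list with `samples`, `tau`,
#'   `percentile`, `n_sims`.
#' @export
null_variability_distribution <- function(untreated_curves, n_sims = 10000L,
                                          percentile = 95, seed = 1L) {
  if (length(untreated_curves) < 2) rlang::abort("need at least 2 replicate plates")
  untreated_curves <- purrr::map(untreated_curves, function(p) {
    if (is.list(p)) p <- do.call(rbind, p)
    if (is.null(nrow(p)) || nrow(p) < 1) rlang::abort("a plate has no eligible untreated wells")
    p
  })
  nt <- unique(purrr::map_int(untreated_curves, ncol))
  if (length(nt) != 1) rlang::abort("plates have mismatched time axes")
  drawn <- withr::with_seed(seed, purrr::map(untreated_curves, function(p) {
    p[sample.int(nrow(p), n_sims, replace = TRUE), , drop = FALSE]
  }))
  hi <- purrr::reduce(drawn, pmax)
  lo <- purrr::reduce(drawn, pmin)
  samples <- rowSums(hi - lo)
  structure(list(samples = samples,
                 tau = unname(stats::quantile(samples, percentile / 100)),
                 percentile = percentile, n_sims = as.integer(n_sims)),
            class = "variability_null")
}

#' @export
print.variability_null <- function(x, ...) {
  cat(sprintf("<variability_null> %d simulations, tau_%g = %g\n",
              x$n_sims, x$percentile, x$tau))
  invisible(x)
}

#' Inter-plate QC decision per condition
#'
#' A condition is flagged as an inter-plate outlier when its observed
#' variability strictly exceeds the resampling null threshold; flagged
#' conditions must not be replicate-merged.
#'
#' @param variability Tibble (or data frame) with columns `condition` and
#'   `V` (observed [inter_plate_variability()] values).
#' @param null A [null_variability_distribution()].
#' @return The input with columns `tau` and `pass` (`FALSE` = outlier) added.
#' @export
inter_plate_qc <- function(variability, null) {
  if (!inherits(null, "variability_null")) rlang::abort("`null` must be a variability_null")
  # an undefined variability (single surviving replicate) cannot be rejected
  dplyr::mutate(tibble::as_tibble(variability), tau = null$tau,
                pass = is.na(.data$V) | .data$V <= null$tau)
}

#' Merge replicate curves of one condition
#'
#' @param curves Replicate-by-time matrix (or list of vectors) of curves.
#' @param keep Logical vector marking surviving replicates (default all).
#' @return Tibble with per-time `mean`, `sd`, and `n_replicates`; `NULL`
#'   (with a warning) when no replicate survives, signalling a dropped
#'   condition.
#' @export
merge_replicates <- function(curves, keep = NULL) {
  if (is.list(curves)) curves <- do.call(rbind, curves)
  keep <- keep %||% rep(TRUE, nrow(curves))
  kept <- curves[keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    rlang::warn("all replicates excluded: condition dropped")
    return(NULL)
  }
  tibble::tibble(time_index = seq_len(ncol(kept)),
                 mean = colMeans(kept),
                 sd = apply(kept, 2, stats::sd),
                 n_replicates = nrow(kept))
}

#' Empirical false-alarm rate of the inter-plate QC
#'
#' Measures the operating characteristic of [inter_plate_qc()] under the
#' null: simulated replicate plates of untreated-model growth curves, a
#' resampling null built from each experiment's untreated wells, and held-out
#' null conditions tested against the threshold. The experiment is repeated
#' `n_experiments` times with fresh noise so the uncertainty of the reported
#' rate is dominated by the binomial error of the total number of conditions
#' tested rather than by the percentile-threshold estimate of any single
#' experiment. With the default 95th percentile the expected rate is 5%.
#'
#' @param n_experiments Independent simulated experiments (default 20).
#' @param n_untreated Untreated wells per plate feeding the resampling null
#'   (default 384, a full plate's worth).
#' @param n_null Held-out null conditions tested per experiment (default 250).
#' @param n_plates Replicate plates per experiment (default 4).
#' @param n_sims,percentile Passed to [null_variability_distribution()].
#' @param seed Master seed.
#' @param ... Curve model parameters passed to [simulate_growth_curves()].
#' @return One-row tibble: `false_alarm_pct`, `n_tested`, `n_flagged`.
#' @export
qc_false_alarm_rate <- function(n_experiments = 20L, n_untreated = 384L,
                                n_null = 250L, n_plates = 4L, n_sims = 10000L,
                                percentile = 95, seed = 1L, ...) {
  flagged <- purrr::map_int(seq_len(n_experiments), function(e) {
    curves <- simulate_growth_curves(n_untreated + n_null, n_plates = n_plates,
                                     seed = derive_seed(seed, 7L * e), ...)
    untr <- purrr::map(curves, function(m) m[seq_len(n_untreated), , drop = FALSE])
    null <- null_variability_distribution(untr, n_sims = n_sims,
                                          percentile = percentile,
                                          seed = derive_seed(seed, 7L * e + 1L))
    test_idx <- n_untreated + seq_len(n_null)
    V <- purrr::map_dbl(test_idx, function(i) {
      inter_plate_variability(do.call(rbind, purrr::map(curves, function(m) m[i, ])))
    })
    sum(V > null$tau)
  })
  n_tested <- n_experiments * n_null
  tibble::tibble(false_alarm_pct = 100 * sum(flagged) / n_tested,
                 n_tested = n_tested, n_flagged = sum(flagged))
}

#' Full inter-plate QC over a plate's conditions
#'
#' Convenience wrapper: computes per-condition variability from long-format
#' replicate curves, builds the untreated resampling null, and applies the
#' threshold. Wells failing intra-plate QC must be removed upstream.
#'
#' @param curves Long tibble with columns `replicate_id`, `condition`,
#'   `time_h`, `delta_confluence`, one row per replicate/condition/time
#'   (untreated wells carry `condition = "UNTREATED"` and a distinguishing
#'   `well` column).
#' @param n_sims,percentile,seed Passed to [null_variability_distribution()].
#' @return List: `flags` tibble (`condition`, `V`, `tau`, `pass`) and `null`.
#' @export
plate_qc <- function(curves, n_sims = 10000L, percentile = 95, seed = 1L) {
  untr <- dplyr::filter(curves, .data$condition == "UNTREATED")
  per_plate <- untr |>
    dplyr::arrange(.data$replicate_id, .data$well, .data$time_h) |>
    dplyr::group_by(.data$replicate_id) |>
    dplyr::group_map(function(d, key) {
      m <- tidyr::pivot_wider(d[, c("well", "time_h", "delta_confluence")],
                              names_from = "time_h", values_from = "delta_confluence")
      as.matrix(m[, -1])
    })
  null <- null_variability_distribution(per_plate, n_sims = n_sims,
                                        percentile = percentile, seed = seed)
  vtab <- curves |>
    dplyr::filter(!.data$condition %in% c("UNTREATED", "BLANK")) |>
    dplyr::arrange(.data$condition, .data$replicate_id, .data$time_h) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(V = {
      n_rep <- dplyr::n_distinct(.data$replicate_id)
      if (n_rep < 2) NA_real_ # single surviving replicate: variability undefined
      else inter_plate_variability(matrix(.data$delta_confluence, nrow = n_rep,
                                          byrow = TRUE))
    }, .groups = "drop")
  list(flags = inter_plate_qc(vtab, null), null = null)
}
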