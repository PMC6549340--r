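# End-point survival index and higher-order Bliss / scaled-Bliss synergy
# scoring with bootstrap resampling significance.
#
# The survival index S is the blank-corrected, control-normalized end-point
# fluorescence: 0 at the blank level, 1 at the untreated level. Under Bliss
# independence a combination's expected survival is the product of its
# single-drug survivals; the Bliss index B = expected - observed is positive
# for synergy. Because one B value can arise from very different
# (expected, observed) pairs, the scaled index B_S = B * (1 - min(expected,
# observed)) suppresses synergies achieved at high observed survival and
# antagonisms predicted at high expected survival.

#' Survival index from end-point fluorescence
#'
#' @param f Fluorescence signal(s) of the measured well(s).
#' @param blanks Numeric vector of blank-well signals.
#' @param controls Numeric vector of untreated-control signals.
#' @return `(f - median(blanks)) / (median(controls) - median(blanks))`,
#'   vectorized over `f`. Not clamped: growth-stimulated wells can exceed 1.
#' @export
survival_index <- function(f, blanks, controls) {
  mb <- stats::median(blanks)
  mc <- stats::median(controls)
  if (!is.finite(mb) || !is.finite(mc) || mc == mb) {
    rlang::abort("degenerate normalization: median(controls) equals median(blanks)")
  }
  (f - mb) / (mc - mb)
}

#' Higher-order Bliss index
#'
#' @param single_S Numeric vector of single-drug survival indices for the
#'   combination's members (length = combination order, at least 2).
#' @param combo_S Observed survival index of the combination.
#' @return `prod(single_S) - combo_S`; positive = synergy, negative =
#'   antagonism, in `[-1, 1]` for survival inputs in `[0, 1]`.
#' @export
bliss_index <- function(single_S, combo_S) {
  if (length(single_S) < 2) rlang::abort("a combination has at least 2 single-drug survivals")
  if (length(combo_S) != 1) rlang::abort("`combo_S` must be a scalar")
  prod(single_S) - combo_S
}

#' Scaled Bliss index
#'
#' `B_S = B * (1 - min(expected, observed))`: equal-B pairs with different
#' survival levels are disambiguated, synergy at high observed survival and
#' antagonism at high expected survival are both suppressed. `|B_S| <= |B|`
#' with equality only when the suppressing survival term is 0.
#'
#' @inheritParams bliss_index
#' @return Scalar scaled Bliss index.
#' @export
scaled_bliss <- function(single_S, combo_S) {
  b <- bliss_index(single_S, combo_S)
  b * (1 - min(prod(single_S), combo_S))
}

#' Bootstrap significance of a scaled Bliss score
#'
#' Resamples replicate survival values with replacement `n_boot` times to
#' form a percentile confidence interval for `B_S`, and computes a two-sided
#' p value against a Bliss-independent null ensemble in which the
#' combination's replicates are replaced by products of independently
#' resampled single-drug replicate draws.
#'
#' @param single_reps List of numeric vectors: replicate survival indices
#'   per member drug (each of length >= 2).
#' @param combo_reps Numeric vector of replicate survival indices of the
#'   combination (length >= 2).
#' @param n_boot Number of bootstrap draws (default 10000).
#' @param seed Seed for the resampling.
#' @param conf Confidence level of the percentile interval (default 0.95).
#' @return One-row tibble: `B`, `B_S`, `ci_lo`, `ci_hi`, `p_value`.
#' @export
synergy_significance <- function(single_reps, combo_reps, n_boot = 10000L,
                                 seed = 1L, conf = 0.95) {
  if (any(lengths(single_reps) < 2) || length(combo_reps) < 2) {
    rlang::abort("need at least 2 replicates per condition",
                 class = "combiscreen_insufficient_replicates")
  }
  singles <- purrr::map_dbl(single_reps, mean)
  obs_B <- bliss_index(singles, mean(combo_reps))
  obs_BS <- scaled_bliss(singles, mean(combo_reps))
  stats <- withr::with_seed(seed, {
    boot_BS <- vapply(seq_len(n_boot), function(i) {
      s <- purrr::map_dbl(single_reps, function(x) mean(sample(x, replace = TRUE)))
      scaled_bliss(s, mean(sample(combo_reps, replace = TRUE)))
    }, numeric(1))
    null_BS <- vapply(seq_len(n_boot), function(i) {
      draws <- purrr::map(single_reps, function(x) sample(x, length(combo_reps), replace = TRUE))
      pseudo_combo <- purrr::reduce(draws, `*`)
      s <- purrr::map_dbl(single_reps, function(x) mean(sample(x, replace = TRUE)))
      scaled_bliss(s, mean(pseudo_combo))
    }, numeric(1))
    list(boot = boot_BS, null = null_BS)
  })
  ci <- stats::quantile(stats$boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  p <- (1 + sum(abs(stats$null) >= abs(obs_BS))) / (n_boot + 1)
  tibble::tibble(B = obs_B, B_S = obs_BS, ci_lo = ci[1], ci_hi = ci[2], p_value = p)
}

#' Score every combination of a replicated screen
#'
#' Computes per-replicate survival indices from end-point fluorescence
#' (normalizing each plate by its own blank and untreated wells), then scores
#' every combination of order 2 or more against the product of its members'
#' single-drug survivals, with bootstrap significance and
#' Benjamini-Hochberg FDR across the combination family.
#'
#' @param measurements Tibble with columns `replicate_id`, `well`, `signal`
#'   (end-point fluorescence per well per replicate plate).
#' @param layouts `plate_layout` tibble covering the same replicates.
#' @param excluded_wells Optional tibble of QC-excluded wells (columns
#'   `replicate_id`, `well`); their measurements are dropped and affected
#'   combinations marked.
#' @param n_boot Bootstrap draws per combination (default 1000; raise for
#'   publication-grade p values).
#' @param seed Master seed (per-combination streams derived from it).
#' @return Tibble, one row per combination: `condition`, `order`, `expected`,
#'   `observed`, `B`, `B_S`, `ci_lo`, `ci_hi`, `p_value`, `fdr`,
#'   `qc_excluded`, `quality_warning` (survival inputs outside `[0, 1]`).
#' @export
plate_synergy_table <- function(measurements, layouts, excluded_wells = NULL,
                                n_boot = 1000L, seed = 1L) {
  d <- dplyr::inner_join(measurements, layouts, by = c("replicate_id", "well"))
  excluded <- tibble::tibble(replicate_id = integer(0), well = character(0))
  if (!is.null(excluded_wells)) excluded <- excluded_wells
  d <- dplyr::anti_join(d, excluded, by = c("replicate_id", "well"))
  # per-replicate-plate survival normalization
  surv <- d |>
    dplyr::group_by(.data$replicate_id) |>
    dplyr::group_modify(function(p, key) {
      blanks <- p$signal[p$condition == "BLANK"]
      controls <- p$signal[p$condition == "UNTREATED"]
      if (length(blanks) == 0 || length(controls) == 0) {
        rlang::abort("each replicate plate needs BLANK and UNTREATED wells")
      }
      dplyr::mutate(p, S = survival_index(.data$signal, blanks, controls))
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(!.data$condition %in% c("BLANK", "UNTREATED"))
  single_reps <- surv |>
    dplyr::filter(.data$order == 1) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(S = list(.data$S), .groups = "drop")
  singles_lookup <- stats::setNames(single_reps$S, single_reps$condition)
  combos <- surv |>
    dplyr::filter(.data$order >= 2) |>
    dplyr::group_by(.data$condition, .data$order) |>
    dplyr::summarise(S = list(.data$S), n_reps = length(.data$S), .groups = "drop") |>
    dplyr::arrange(.data$order, .data$condition)
  excluded_conditions <- unique(dplyr::inner_join(layouts, excluded,
                                                  by = c("replicate_id", "well"))$condition)
  rows <- purrr::pmap(list(combos$condition, combos$order, combos$S, seq_len(nrow(combos))),
                      function(cond, ord, combo_S, i) {
    members <- strsplit(cond, "+", fixed = TRUE)[[1]]
    missing <- setdiff(members, names(singles_lookup))
    if (length(missing)) {
      rlang::abort(paste0("single-drug wells missing for: ", paste(missing, collapse = ", ")),
                   class = "combiscreen_missing_reference")
    }
    sr <- singles_lookup[members]
    expected <- prod(purrr::map_dbl(sr, mean))
    observed <- mean(combo_S)
    sig <- if (length(combo_S) >= 2 && all(lengths(sr) >= 2)) {
      synergy_significance(sr, combo_S, n_boot = n_boot, seed = derive_seed(seed, i))
    } else {
      tibble::tibble(B = bliss_index(purrr::map_dbl(sr, mean), observed),
                     B_S = scaled_bliss(purrr::map_dbl(sr, mean), observed),
                     ci_lo = NA_real_, ci_hi = NA_real_, p_value = NA_real_)
    }
    dplyr::bind_cols(
      tibble::tibble(condition = cond, order = ord, expected = expected,
                     observed = observed),
      sig,
      tibble::tibble(
        qc_excluded = cond %in% excluded_conditions ||
          any(members %in% excluded_conditions),
        quality_warning = any(unlist(sr) < 0 | unlist(sr) > 1) ||
          any(combo_S < 0 | combo_S > 1)
      )
    )
  })
  out <- purrr::list_rbind(rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("synergy_table", class(out))
  out
}
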