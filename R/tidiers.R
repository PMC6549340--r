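# broom-style tidy()/glance() methods for the package's fitted objects.

#' Tidy a tuned matched filter
#'
#' @param x A [build_filter()] model.
#' @param ... Unused.
#' @return The cross-validation tuning report, one row per (repeat, fold):
#'   `repeat_id`, `fold`, `tau_j`, `train_loss`, `test_loss`; empty tibble
#'   when untuned.
#' @export
tidy.matched_filter <- function(x, ...) {
  x$tuning %||% tibble::tibble(repeat_id = integer(0), fold = integer(0),
                               tau_j = numeric(0), train_loss = numeric(0),
                               test_loss = numeric(0))
}

#' @rdname tidy.matched_filter
#' @return `glance()` returns a one-row summary: patch size, background
#'   level, threshold, and median held-out tuning loss.
#' @export
glance.matched_filter <- function(x, ...) {
  tibble::tibble(
    patch_rows = nrow(x$w), patch_cols = ncol(x$w), b = x$b,
    tau = x$tau %||% NA_real_,
    median_test_loss = if (is.null(x$tuning)) NA_real_ else stats::median(x$tuning$test_loss)
  )
}

#' Tidy a cluster tree
#'
#' @param x A [multilevel_cluster()] tree.
#' @param ... Unused.
#' @return Leaf membership: tibble with `node` and `condition`, one row per
#'   condition.
#' @export
tidy.cluster_tree <- function(x, ...) {
  rep_tbl <- group_report(x)
  dplyr::filter(rep_tbl, .data$is_leaf) |>
    dplyr::select("node", "members") |>
    tidyr::unnest_longer("members", values_to = "condition")
}

#' @rdname tidy.cluster_tree
#' @export
glance.cluster_tree <- function(x, ...) {
  rep_tbl <- group_report(x)
  tibble::tibble(n_conditions = length(x$members),
                 n_nodes = nrow(rep_tbl),
                 n_leaves = sum(rep_tbl$is_leaf),
                 depth = max(rep_tbl$depth))
}

#' Tidy a resampling variability null
#'
#' @param x A [null_variability_distribution()].
#' @param ... Unused.
#' @return Tibble of the simulated variability values (`sim`, `V`).
#' @export
tidy.variability_null <- function(x, ...) {
  tibble::tibble(sim = seq_along(x$samples), V = x$samples)
}

#' @rdname tidy.variability_null
#' @export
glance.variability_null <- function(x, ...) {
  tibble::tibble(n_sims = x$n_sims, percentile = x$percentile, tau = x$tau)
}
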