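# Automated randomized 384-well layout design for drug combination screens.
#
# A screen evaluates every subset (up to a chosen order) of a fixed drug
# panel, one fixed concentration per drug. Each condition occupies one well
# per plate; layouts are independently randomized across replicate plates so
# spatially correlated noise decorrelates between replicates.

#' Define a drug panel
#'
#' @param name Character vector of unique drug names.
#' @param concentration Positive numeric vector of fixed assay
#'   concentrations, one per drug.
#' @param unit Concentration unit string(s), recycled (default `"uM"`).
#' @return A tibble with columns `name`, `concentration`, `unit`.
#' @export
#' @examples
#' drug_panel(c("Apr", "Dis"), c(2.6, 0.67))
drug_panel <- function(name, concentration, unit = "uM") {
  name <- as.character(name)
  if (length(name) == 0) rlang::abort("panel must contain at least one drug")
  if (anyDuplicated(name)) rlang::abort("drug names must be unique")
  if (length(concentration) != length(name)) {
    rlang::abort("`concentration` must have one value per drug")
  }
  if (!all(is.finite(concentration) & concentration > 0)) {
    rlang::abort("concentrations must be positive and finite")
  }
  tibble::tibble(name = name, concentration = as.numeric(concentration),
                 unit = rep_len(as.character(unit), length(name)))
}

#' Number of wells for an exhaustive combination experiment
#'
#' Counts all non-empty drug subsets of size at most `max_order` drawn from a
#' panel of `n_drugs` drugs: `sum(choose(n_drugs, 1:max_order))`. This is the
#' number of treated wells an exhaustive screen needs.
#'
#' @param n_drugs Number of drugs in the panel.
#' @param max_order Highest combination order to include.
#' @return Integer well count.
#' @export
#' @examples
#' n_wells(9, 4) # 255: one 384-well plate fits this plus 40+ controls
n_wells <- function(n_drugs, max_order) {
  if (length(n_drugs) != 1 || length(max_order) != 1 ||
      n_drugs < 1 || max_order < 1 || max_order != round(max_order) ||
      n_drugs != round(n_drugs) || max_order > n_drugs) {
    rlang::abort("need integers 1 <= max_order <= n_drugs")
  }
  as.integer(sum(choose(n_drugs, seq_len(max_order))))
}

combo_label <- function(members) paste(members, collapse = "+")

#' Enumerate all combinations of a panel up to a given order
#'
#' @param panel A [drug_panel()].
#' @param max_order Highest order to enumerate.
#' @return A tibble with one row per combination: `condition` (label with
#'   members joined by `+`), `order`, and `members` (list column of sorted
#'   member names). Rows are ordered by ascending order, then
#'   lexicographically by member names, so the enumeration is deterministic.
#' @export
enumerate_combinations <- function(panel, max_order) {
  if (nrow(panel) == 0) rlang::abort("empty panel")
  n_wells(nrow(panel), max_order) # validates bounds
  nm <- sort(panel$name)
  members <- unlist(purrr::map(seq_len(max_order), function(k) {
    asplit(utils::combn(nm, k), 2)
  }), recursive = FALSE)
  members <- purrr::map(members, as.character)
  tibble::tibble(
    condition = vapply(members, combo_label, ""),
    order = vapply(members, length, integer(1)),
    members = members
  )
}

#' Specify a combination screen design
#'
#' @param panel A [drug_panel()].
#' @param max_order Highest combination order (`exhaustive` mode).
#' @param mode `"exhaustive"` (all subsets up to `max_order`), `"pairwise"`
#'   (singles and pairs), or `"explicit"` (conditions given in
#'   `combinations`).
#' @param replicates Number of replicate plates.
#' @param combinations For `"explicit"` mode, a list of character vectors of
#'   member drug names.
#' @param min_untreated Feasibility floor for untreated control wells per
#'   plate (default 40).
#' @param untreated_target Untreated wells actually placed when space allows
#'   (default 53); remaining wells are BLANK (assay blanks).
#' @param plate_wells Plate capacity (default 384).
#' @param edge_exclude If `TRUE`, no condition is placed on the outer rim of
#'   the plate (rows A/P, columns 1/24).
#' @param seed Master seed; replicate `r` uses stream `seed + r`.
#' @return A `design_spec` object (list).
#' @export
design_spec <- function(panel, max_order = NULL,
                        mode = c("exhaustive", "pairwise", "explicit"),
                        replicates = 1L, combinations = NULL,
                        min_untreated = 40L, untreated_target = 53L,
                        plate_wells = 384L, edge_exclude = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  if (min_untreated < 0) rlang::abort("min_untreated must be >= 0")
  if (replicates < 1) rlang::abort("replicates must be >= 1")
  conditions <- switch(mode,
    exhaustive = enumerate_combinations(panel, max_order),
    pairwise = enumerate_combinations(panel, min(2L, nrow(panel))),
    explicit = {
      if (is.null(combinations)) rlang::abort("explicit mode needs `combinations`")
      members <- purrr::map(combinations, function(m) sort(as.character(m)))
      bad <- purrr::map_lgl(members, function(m) !all(m %in% panel$name) || anyDuplicated(m) > 0)
      if (any(bad)) rlang::abort("explicit combinations must be unique subsets of the panel")
      tibble::tibble(condition = vapply(members, combo_label, ""),
                     order = lengths(members), members = members) |>
        dplyr::arrange(.data$order, .data$condition)
    }
  )
  if (anyDuplicated(conditions$condition)) rlang::abort("duplicate combinations in design")
  structure(
    list(panel = panel, mode = mode,
         max_order = if (is.null(max_order)) max(conditions$order, 0L) else as.integer(max_order),
         conditions = conditions, replicates = as.integer(replicates),
         min_untreated = as.integer(min_untreated),
         untreated_target = as.integer(untreated_target),
         plate_wells = as.integer(plate_wells),
         edge_exclude = isTRUE(edge_exclude), seed = as.integer(seed)),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> %d drugs, mode %s, %d conditions, %d replicate plate(s), seed %d\n",
              nrow(x$panel), x$mode, nrow(x$conditions), x$replicates, x$seed))
  invisible(x)
}

# Wells available for assignment under the spec's edge policy.
candidate_wells <- function(spec) {
  w <- all_wells(spec$plate_wells)
  if (spec$edge_exclude) {
    pw <- parse_well(w)
    w <- w[pw$row > 1 & pw$row < PLATE_ROWS & pw$col > 1 & pw$col < PLATE_COLS]
  }
  w
}

#' Check spatial feasibility of a design
#'
#' A design fits one plate when treated conditions plus the untreated floor
#' do not exceed plate capacity. An infeasible design is not an error: the
#' report suggests the minimum number of plates over which a balanced split
#' of the conditions becomes feasible.
#'
#' @param spec A [design_spec()].
#' @return A one-row tibble: `n_treated`, `min_untreated`, `capacity`,
#'   `feasible`, `n_plates` (suggested), `per_plate` (max conditions per
#'   plate under a balanced split), `note`.
#' @export
check_feasibility <- function(spec) {
  n_treated <- nrow(spec$conditions)
  capacity <- length(candidate_wells(spec))
  feasible <- n_treated + spec$min_untreated <= capacity
  p <- 1L
  while (ceiling(n_treated / p) + spec$min_untreated > capacity) p <- p + 1L
  note <- if (n_treated == 0) {
    "design contains no treated conditions"
  } else if (feasible) {
    "fits on one plate"
  } else {
    sprintf("split across %d plates (<= %d conditions each)", p, ceiling(n_treated / p))
  }
  if (n_treated == 0) rlang::warn("design contains no treated conditions")
  tibble::tibble(n_treated = n_treated, min_untreated = spec$min_untreated,
                 capacity = capacity, feasible = feasible, n_plates = p,
                 per_plate = as.integer(ceiling(n_treated / max(p, 1L))), note = note)
}

#' Generate one randomized replicate plate layout
#'
#' Every condition (all combinations plus the untreated controls) is placed
#' at a uniformly random well, independently per replicate plate; leftover
#' wells are BLANK. The permutation is seeded from `spec$seed + replicate_id`
#' so the same call is reproducible while replicates get independent layouts.
#'
#' @param spec A feasible [design_spec()].
#' @param replicate_id Integer replicate plate index (1-based).
#' @return A tibble (class `plate_layout`) with columns `replicate_id`,
#'   `well`, `row`, `col`, `condition` (combination label, `"UNTREATED"` or
#'   `"BLANK"`), `order` (0 for untreated, `NA` for blank).
#' @export
randomize_layout <- function(spec, replicate_id = 1L) {
  report <- suppressWarnings(check_feasibility(spec))
  if (!report$feasible) {
    rlang::abort(
      sprintf("design infeasible on one plate: %d treated + %d untreated > %d wells; suggested: %s",
              report$n_treated, report$min_untreated, report$capacity, report$note),
      class = "combiscreen_layout_infeasible", report = report
    )
  }
  wells <- candidate_wells(spec)
  n_untr <- min(max(spec$min_untreated, spec$untreated_target),
                length(wells) - report$n_treated)
  cond <- c(spec$conditions$condition, rep("UNTREATED", n_untr))
  ord <- c(spec$conditions$order, rep(0L, n_untr))
  pos <- withr::with_seed(derive_seed(spec$seed, replicate_id),
                          sample(length(wells), length(cond)))
  plate <- all_wells(spec$plate_wells)
  condition <- stats::setNames(rep("BLANK", length(plate)), plate)
  order <- stats::setNames(rep(NA_integer_, length(plate)), plate)
  condition[wells[pos]] <- cond
  order[wells[pos]] <- ord
  pw <- parse_well(plate)
  out <- tibble::tibble(replicate_id = as.integer(replicate_id), well = plate,
                        row = pw$row, col = pw$col,
                        condition = unname(condition), order = unname(order))
  class(out) <- c("plate_layout", class(out))
  out
}

#' Generate layouts for all replicate plates of a design
#'
#' @inheritParams randomize_layout
#' @return A tibble of row-bound [randomize_layout()] results, one block per
#'   replicate plate.
#' @export
design_layouts <- function(spec) {
  out <- purrr::map(seq_len(spec$replicates), function(r) randomize_layout(spec, r)) |>
    purrr::list_rbind()
  class(out) <- c("plate_layout", class(out))
  out
}
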