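# Text formats around the design module: the experiment specification file,
# the per-replicate destination (transfer) CSV, and the layout map CSV that
# all downstream modules consume.

#' Read / write an experiment specification file
#'
#' The specification is a line-oriented text file: `key=value` header lines
#' (`mode`, `max_order`, `replicates`, `seed`, and optionally
#' `min_untreated`, `untreated_target`, `plate_wells`, `edge_exclude`)
#' followed by one tab-separated `drug<TAB>concentration<TAB>unit` line per
#' panel drug. Lines starting with `#` and blank lines are ignored.
#'
#' @param path File path.
#' @return `read_design_spec()` returns a [design_spec()].
#' @export
read_design_spec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  is_kv <- grepl("=", lines, fixed = TRUE) & !grepl("\t", lines, fixed = TRUE)
  kv <- strsplit(lines[is_kv], "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  hdr <- stats::setNames(as.list(vals), keys)
  known <- c("mode", "max_order", "replicates", "seed", "min_untreated",
             "untreated_target", "plate_wells", "edge_exclude")
  if (length(bad <- setdiff(keys, known))) {
    rlang::abort(paste0("unknown specification key(s): ", paste(bad, collapse = ", ")))
  }
  drug_lines <- strsplit(lines[!is_kv], "\t", fixed = TRUE)
  if (length(drug_lines) == 0) rlang::abort("specification lists no drugs")
  if (any(lengths(drug_lines) < 2)) rlang::abort("drug lines need drug<TAB>concentration[<TAB>unit]")
  panel <- drug_panel(
    name = vapply(drug_lines, `[`, "", 1L),
    concentration = as.numeric(vapply(drug_lines, `[`, "", 2L)),
    unit = vapply(drug_lines, function(x) if (length(x) >= 3) x[3] else "uM", "")
  )
  get <- function(key, default, f = identity) if (is.null(hdr[[key]])) default else f(hdr[[key]])
  design_spec(
    panel,
    max_order = get("max_order", nrow(panel), as.integer),
    mode = get("mode", "exhaustive"),
    replicates = get("replicates", 1L, as.integer),
    min_untreated = get("min_untreated", 40L, as.integer),
    untreated_target = get("untreated_target", 53L, as.integer),
    plate_wells = get("plate_wells", 384L, as.integer),
    edge_exclude = get("edge_exclude", FALSE, function(x) tolower(x) %in% c("true", "1", "yes")),
    seed = get("seed", 1L, as.integer)
  )
}

#' @rdname read_design_spec
#' @param spec A [design_spec()].
#' @export
write_design_spec <- function(spec, path) {
  hdr <- c(
    sprintf("mode=%s", spec$mode),
    sprintf("max_order=%d", spec$max_order),
    sprintf("replicates=%d", spec$replicates),
    sprintf("seed=%d", spec$seed),
    sprintf("min_untreated=%d", spec$min_untreated),
    sprintf("untreated_target=%d", spec$untreated_target),
    sprintf("plate_wells=%d", spec$plate_wells),
    sprintf("edge_exclude=%s", tolower(spec$edge_exclude))
  )
  drugs <- sprintf("%s\t%s\t%s", spec$panel$name, format(spec$panel$concentration,
                   trim = TRUE, scientific = FALSE), spec$panel$unit)
  writeLines(c(hdr, drugs), path)
  invisible(path)
}

#' Export a layout as a destination (transfer) CSV
#'
#' One row per (well, compound) transfer with columns `plate_id`,
#' `destination_well`, `compound`, `final_concentration`, `unit`; a treated
#' well of order n yields n rows. Untreated and blank wells are emitted as
#' single marker rows (`compound` = `UNTREATED` / `BLANK`, concentration
#' `NA`) so the exported file round-trips losslessly through
#' [read_destination_csv()].
#'
#' @param layout A single-replicate [randomize_layout()] tibble.
#' @param panel The [drug_panel()] supplying concentrations.
#' @param path Output CSV path.
#' @param plate_id Plate identifier written in every row; defaults to
#'   `"R<replicate_id>"`.
#' @return `path`, invisibly.
#' @export
export_destination_csv <- function(layout, panel, path,
                                   plate_id = sprintf("R%d", layout$replicate_id[1])) {
  rows <- layout |>
    dplyr::mutate(compound = purrr::map(.data$condition, function(cond) {
      if (cond %in% c("UNTREATED", "BLANK")) cond else strsplit(cond, "+", fixed = TRUE)[[1]]
    })) |>
    tidyr::unnest_longer("compound") |>
    dplyr::left_join(panel, by = c(compound = "name")) |>
    dplyr::transmute(plate_id = plate_id, destination_well = .data$well,
                     compound = .data$compound,
                     final_concentration = .data$concentration, unit = .data$unit)
  unknown <- setdiff(rows$compound, c(panel$name, "UNTREATED", "BLANK"))
  if (length(unknown)) {
    rlang::abort(paste0("layout refers to drugs missing from the panel: ",
                        paste(unknown, collapse = ", ")))
  }
  readr::write_csv(rows, path)
  invisible(path)
}

#' Read a destination CSV back into a plate layout
#'
#' @param path CSV written by [export_destination_csv()].
#' @param replicate_id Replicate index recorded on the layout (default 1).
#' @return A `plate_layout` tibble equivalent to the exported one.
#' @export
read_destination_csv <- function(path, replicate_id = 1L) {
  rows <- readr::read_csv(path, show_col_types = FALSE)
  per_well <- rows |>
    dplyr::group_by(.data$destination_well) |>
    dplyr::summarise(condition = if (dplyr::n() == 1 && .data$compound[1] %in% c("UNTREATED", "BLANK")) {
      .data$compound[1]
    } else {
      combo_label(sort(.data$compound))
    }, .groups = "drop")
  pw <- parse_well(per_well$destination_well)
  out <- tibble::tibble(replicate_id = as.integer(replicate_id),
                        well = per_well$destination_well,
                        row = pw$row, col = pw$col, condition = per_well$condition) |>
    dplyr::mutate(order = dplyr::case_when(
      .data$condition == "UNTREATED" ~ 0L,
      .data$condition == "BLANK" ~ NA_integer_,
      TRUE ~ lengths(strsplit(.data$condition, "+", fixed = TRUE))
    )) |>
    dplyr::arrange(.data$row, .data$col)
  class(out) <- c("plate_layout", class(out))
  out
}

#' Write / read the human-readable layout map
#'
#' The layout map (`replicate_id`, `well`, `condition`, `order`) is the file
#' every downstream stage uses to look up what each well contains.
#'
#' @param layout A `plate_layout` tibble (one or more replicates).
#' @param path CSV path.
#' @export
write_layout_map <- function(layout, path) {
  readr::write_csv(dplyr::select(layout, "replicate_id", "well", "condition", "order"), path)
  invisible(path)
}

#' @rdname write_layout_map
#' @export
read_layout_map <- function(path) {
  map <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(order = readr::col_integer()))
  pw <- parse_well(map$well)
  out <- dplyr::mutate(map, row = pw$row, col = pw$col, .after = "well")
  class(out) <- c("plate_layout", class(out))
  out
}
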