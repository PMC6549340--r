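# Run configuration and end-to-end orchestration: per replicate plate,
# intra-plate QC -> feature extraction -> matched-filter counts -> survival;
# then inter-plate QC -> replicate merging -> response mining. Every random
# decision derives from the master seed and a run manifest records the
# configuration.

run_config_defaults <- function() {
  list(
    paths = list(images = NULL, layout = NULL, fmca = NULL, prototype = NULL,
                 out = "results"),
    seed = 1L,
    features = list(n_levels = 3L, n_bins = 16L, scale_reduction = 2),
    matched_filter = list(tau = NULL, folds = 4L, repeats = 2L, overfit_cutoff = 5),
    qc = list(n_sims = 10000L, percentile = 95, n_mad = 3),
    synergy = list(n_boot = 1000L),
    mining = list(max_depth = 2L, min_size = 8L, repeats = 10L, drop_pct = 20)
  )
}

#' Load a pipeline run configuration
#'
#' The configuration is a YAML file mirroring the module parameters (blocks
#' `paths`, `features`, `matched_filter`, `qc`, `synergy`, `mining`, plus the
#' master `seed`). Unknown keys are rejected; omitted keys take the package
#' defaults.
#'
#' @param path YAML file, or a list with the same structure.
#' @return A validated `run_config` list.
#' @export
run_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- run_config_defaults()
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) rlang::abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  cfg <- defaults
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      bad2 <- setdiff(names(user[[k]]), names(defaults[[k]]))
      if (length(bad2)) {
        rlang::abort(paste0("unknown config key(s) in `", k, "`: ", paste(bad2, collapse = ", ")))
      }
      cfg[[k]] <- utils::modifyList(defaults[[k]], user[[k]])
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  structure(cfg, class = "run_config")
}

# Per-replicate stage: QC + features + counts for one plate's frames.
analyze_replicate <- function(frames_by_well, times_h, cfg, model = NULL) {
  feats <- plate_features(frames_by_well, times_h = times_h,
                          n_levels = cfg$features$n_levels,
                          n_bins = cfg$features$n_bins,
                          scale_reduction = cfg$features$scale_reduction)
  intra <- intra_plate_qc(attr(feats, "phhc_t0"), n_mad = cfg$qc$n_mad)
  keep <- intra$well[intra$pass]
  feats_kept <- dplyr::filter(feats, .data$well %in% keep)
  counts <- NULL
  if (!is.null(model) && !is.null(model$tau)) {
    counts <- purrr::list_rbind(purrr::map(keep, function(w) {
      well_counts(frames_by_well[[w]], model, times_h = times_h, well = w)
    }))
  }
  list(features = feats_kept, intra = intra, counts = counts)
}

#' Run the full analysis pipeline
#'
#' Executes, per replicate plate: intra-plate QC on first-frame morphology
#' features, confluence/morphology feature extraction, and (when a tuned
#' matched-filter model is available) object counting; then across plates:
#' resampling-based inter-plate QC, replicate merging, synergy scoring, and
#' multilevel response mining. All result tables are written as CSV under
#' `cfg$paths$out` together with a `manifest.yaml` recording configuration
#' and seed.
#'
#' @param cfg A [run_config()] (or path to one).
#' @param model Optional tuned [build_filter()] model (otherwise counts are
#'   all zero placeholders are omitted and mining uses a zero count block).
#' @return Invisible list of the in-memory results (`features`, `intra`,
#'   `counts`, `inter`, `merged`, `synergy`, `mining`).
#' @export
run_pipeline <- function(cfg, model = NULL) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  for (p in c("images", "layout", "fmca")) {
    if (is.null(cfg$paths[[p]])) rlang::abort(sprintf("config paths$%s is required", p))
  }
  out_dir <- cfg$paths$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  layouts <- read_layout_map(cfg$paths$layout)
  manifest <- read_image_set(cfg$paths$images)
  plates <- sort(unique(manifest$plate))
  rep_of <- function(plate) as.integer(sub("^R", "", plate))

  per_rep <- purrr::map(plates, function(plate) {
    wells <- unique(manifest$well[manifest$plate == plate])
    frames_by_well <- purrr::map(wells, function(w) load_well_frames(manifest, plate, w))
    names(frames_by_well) <- wells
    n_frames <- max(manifest$frame[manifest$plate == plate])
    times_h <- seq(4, by = 4, length.out = n_frames)
    res <- analyze_replicate(frames_by_well, times_h, cfg, model = model)
    res$replicate_id <- rep_of(plate)
    res
  })
  features <- purrr::list_rbind(purrr::map(per_rep, function(r) {
    dplyr::mutate(r$features, replicate_id = r$replicate_id, .before = 1)
  }))
  intra <- purrr::list_rbind(purrr::map(per_rep, function(r) {
    dplyr::mutate(r$intra, replicate_id = r$replicate_id, .before = 1)
  }))
  counts <- purrr::list_rbind(purrr::map(per_rep, function(r) {
    if (is.null(r$counts)) NULL else dplyr::mutate(r$counts, replicate_id = r$replicate_id, .before = 1)
  }))

  # inter-plate QC on condition growth curves (wells passing intra QC only)
  curves <- features |>
    dplyr::inner_join(dplyr::select(layouts, "replicate_id", "well", "condition", "order"),
                      by = c("replicate_id", "well"))
  qc_res <- plate_qc(curves, n_sims = cfg$qc$n_sims, percentile = cfg$qc$percentile,
                     seed = cfg$seed)
  excluded_wells <- dplyr::select(dplyr::filter(intra, !.data$pass), "replicate_id", "well")

  merged <- curves |>
    dplyr::filter(!.data$condition %in% c("BLANK"),
                  !.data$condition %in% qc_res$flags$condition[!qc_res$flags$pass]) |>
    dplyr::group_by(.data$condition, .data$time_h) |>
    dplyr::summarise(
      delta_confluence = mean(.data$delta_confluence),
      delta_morphology = mean(.data$delta_morphology),
      n_replicates = dplyr::n(), .groups = "drop")

  fmca <- readr::read_csv(cfg$paths$fmca, show_col_types = FALSE)
  synergy <- plate_synergy_table(fmca, layouts, excluded_wells = excluded_wells,
                                 n_boot = cfg$synergy$n_boot, seed = cfg$seed)

  # fused profiles for mining: merged curves + merged counts + mean survival
  surv <- fmca |>
    dplyr::inner_join(dplyr::select(layouts, "replicate_id", "well", "condition"),
                      by = c("replicate_id", "well")) |>
    dplyr::group_by(.data$replicate_id) |>
    dplyr::group_modify(function(p, key) {
      dplyr::mutate(p, S = survival_index(.data$signal,
                                          p$signal[p$condition == "BLANK"],
                                          p$signal[p$condition == "UNTREATED"]))
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(!.data$condition %in% c("BLANK")) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(viability = mean(.data$S), .groups = "drop")
  count_profiles <- if (!is.null(counts)) {
    counts |>
      dplyr::inner_join(dplyr::select(layouts, "replicate_id", "well", "condition"),
                        by = c("replicate_id", "well")) |>
      dplyr::group_by(.data$condition, .data$time_h) |>
      dplyr::summarise(mean_count = mean(.data$mean_count), .groups = "drop")
  } else {
    dplyr::mutate(dplyr::distinct(merged, .data$condition, .data$time_h), mean_count = 0)
  }
  profiles <- merged |>
    dplyr::inner_join(count_profiles, by = c("condition", "time_h")) |>
    dplyr::filter(.data$condition != "UNTREATED") |>
    dplyr::arrange(.data$condition, .data$time_h) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(dC = list(.data$delta_confluence),
                     dM = list(.data$delta_morphology),
                     counts = list(.data$mean_count), .groups = "drop") |>
    dplyr::inner_join(surv, by = "condition")
  mining <- if (nrow(profiles) >= 2) {
    mine_responses(profiles, max_depth = cfg$mining$max_depth,
                   min_size = cfg$mining$min_size, repeats = cfg$mining$repeats,
                   drop_pct = cfg$mining$drop_pct, seed = cfg$seed)
  } else NULL

  readr::write_csv(features, file.path(out_dir, "features.csv"))
  readr::write_csv(intra, file.path(out_dir, "qc_intra.csv"))
  if (!is.null(counts)) readr::write_csv(counts, file.path(out_dir, "counts.csv"))
  readr::write_csv(qc_res$flags, file.path(out_dir, "qc_inter.csv"))
  readr::write_csv(merged, file.path(out_dir, "merged_curves.csv"))
  readr::write_csv(dplyr::select(synergy, -dplyr::any_of("centers")),
                   file.path(out_dir, "synergy.csv"))
  if (!is.null(mining)) {
    membership <- tidyr::unnest_longer(
      dplyr::select(dplyr::filter(group_report(mining$tree), .data$is_leaf),
                    "node", "members"), "members")
    readr::write_csv(membership, file.path(out_dir, "mining_membership.csv"))
    reps_tbl <- tidyr::unnest_longer(
      dplyr::select(group_report(mining$tree), "node", "representatives"),
      "representatives")
    readr::write_csv(reps_tbl, file.path(out_dir, "mining_representatives.csv"))
  }
  yaml::write_yaml(list(seed = cfg$seed, config = unclass(cfg),
                        package = as.character(utils::packageVersion("combiscreen"))),
                   file.path(out_dir, "manifest.yaml"))
  invisible(list(features = features, intra = intra, counts = counts,
                 inter = qc_res, merged = merged, synergy = synergy,
                 mining = mining))
}
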