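# Seeded synthetic-data generators: textured background frames, planted
# prototype-like objects with ground truth, per-well growth-curve series, and
# whole replicate plates (images + end-point fluorescence), so every analysis
# stage can be exercised and scored without microscope data.

#' Synthetic textured background frame
#'
#' Emulates the flat, low-noise background of a phase-contrast well: a
#' constant field plus Gaussian sensor noise, quantized to 8-bit gray levels
#' (as camera output is). With the default sub-level noise most pixels sit
#' exactly at `level` with sparse one-level speckle, so adaptive segmentation
#' of a pure-background frame marks almost nothing as foreground.
#'
#' @param shape Integer (rows, cols) of the frame.
#' @param level Mean background intensity on the `[0, 1]` scale.
#' @param noise_sd Gaussian noise standard deviation before quantization
#'   (default 0.002, about half an 8-bit gray level).
#' @param seed Seed.
#' @return Numeric matrix on the `[0, 1]` scale, quantized to 1/255 steps.
#' @export
make_background <- function(shape = c(96L, 96L), level = 0.4, noise_sd = 0.002,
                            seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 1), noise_sd >= 0)
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(prod(shape), level, noise_sd), shape[1], shape[2])
    round(pmin(pmax(x, 0), 1) * 255) / 255
  })
}

#' Apoptotic-like object template
#'
#' A bright elliptical ring around a darker core, the visual signature of a
#' rounded apoptotic-like cell in phase contrast. The template holds additive
#' intensity offsets (added onto the background).
#'
#' @param height,width Template size in pixels (default 33 x 32).
#' @param ring Peak ring brightness offset (default 0.35).
#' @param core Core darkness offset (default -0.15).
#' @return Numeric `height` x `width` matrix of offsets.
#' @export
object_template <- function(height = 33L, width = 32L, ring = 0.35, core = -0.15) {
  r <- (seq_len(height) - (height + 1) / 2) / (height / 2)
  c <- (seq_len(width) - (width + 1) / 2) / (width / 2)
  rad <- sqrt(outer(r^2, c^2, `+`))
  tpl <- matrix(0, height, width)
  tpl[rad <= 0.45] <- core
  band <- rad > 0.55 & rad <= 0.95
  tpl[band] <- ring * (1 - abs(rad[band] - 0.75) / 0.2)
  tpl
}

#' Plant template objects at known positions
#'
#' @param frame Background frame.
#' @param template Additive template matrix (see [object_template()]).
#' @param centers Two-column matrix or data frame of (row, col) object
#'   centers; templates must fit fully inside the frame.
#' @return List: `frame` (with objects blended in, clipped to `[0, 1]`),
#'   `truth` (tibble of centers with `overlapping` flags).
#' @export
plant_objects <- function(frame, template, centers) {
  centers <- as.matrix(centers)
  if (nrow(centers) == 0) {
    return(list(frame = frame,
                truth = tibble::tibble(row = integer(0), col = integer(0),
                                       overlapping = logical(0))))
  }
  re <- center_extent(nrow(template))
  ce <- center_extent(ncol(template))
  occupied <- matrix(FALSE, nrow(frame), ncol(frame))
  overlapping <- logical(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    rows <- (centers[i, 1] - re[1]):(centers[i, 1] + re[2])
    cols <- (centers[i, 2] - ce[1]):(centers[i, 2] + ce[2])
    if (min(rows) < 1 || max(rows) > nrow(frame) || min(cols) < 1 || max(cols) > ncol(frame)) {
      rlang::abort("planted object does not fit inside the frame")
    }
    if (any(occupied[rows, cols])) {
      overlapping[i] <- TRUE
      rlang::warn(sprintf("planted object %d overlaps an earlier one", i))
    }
    occupied[rows, cols] <- TRUE
    frame[rows, cols] <- frame[rows, cols] + template
  }
  frame <- pmin(pmax(frame, 0), 1)
  list(frame = frame,
       truth = tibble::tibble(row = centers[, 1], col = centers[, 2],
                              overlapping = overlapping))
}

#' Random object centers with a minimum separation
#'
#' Draws `n` centers uniformly such that a `template_shape` patch fits fully
#' inside the frame at each and centers are at least `sep` pixels apart on at
#' least one axis (default: just over the template diagonal, so planted
#' objects never overlap). Draw inside a seed context for reproducibility.
#'
#' @param n Number of centers.
#' @param frame_shape,template_shape Integer (rows, cols) sizes.
#' @param sep Minimum separation in pixels.
#' @param max_tries Rejection-sampling budget.
#' @return Two-column matrix of (row, col) centers.
#' @export
random_centers <- function(n, frame_shape, template_shape, sep = NULL, max_tries = 2000L) {
  re <- center_extent(template_shape[1])
  ce <- center_extent(template_shape[2])
  sep <- sep %||% ceiling(sqrt(sum(template_shape^2))) + 1L
  centers <- matrix(integer(0), ncol = 2)
  tries <- 0L
  while (nrow(centers) < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- c(sample((1 + re[1]):(frame_shape[1] - re[2]), 1),
              sample((1 + ce[1]):(frame_shape[2] - ce[2]), 1))
    if (nrow(centers) == 0 ||
        all(abs(centers[, 1] - cand[1]) > sep | abs(centers[, 2] - cand[2]) > sep)) {
      centers <- rbind(centers, cand)
    }
  }
  if (nrow(centers) < n) rlang::abort("could not place the requested objects without crowding")
  unname(centers)
}

#' Simulate untreated growth curves for replicate plates
#'
#' Emulates the relative confluence change of untreated wells: exponential
#' growth relative to the first recorded frame plus i.i.d. Gaussian
#' measurement noise (zero at the reference frame by construction). Used to
#' study the inter-plate QC under the null.
#'
#' @param n_wells Wells per plate.
#' @param n_plates Replicate plates.
#' @param times_h Recording times in hours (default 17 frames, 4 h apart).
#' @param growth_rate Exponential growth rate per hour (default 0.02, about a
#'   3.6-fold confluence gain over 64 h).
#' @param noise_sd Measurement noise sd on the relative-change scale
#'   (default 0.05).
#' @param seed Seed.
#' @return List of `n_plates` matrices (`n_wells` x `length(times_h)`).
#' @export
simulate_growth_curves <- function(n_wells, n_plates = 1L, times_h = seq(4, 68, by = 4),
                                   growth_rate = 0.02, noise_sd = 0.05, seed = 1L) {
  base <- exp(growth_rate * (times_h - times_h[1])) - 1
  withr::with_seed(seed, {
    purrr::map(seq_len(n_plates), function(p) {
      noise <- matrix(stats::rnorm(n_wells * length(times_h), 0, noise_sd),
                      n_wells, length(times_h))
      noise[, 1] <- 0
      sweep(noise, 2, base, `+`)
    })
  })
}

#' Single-drug effect model for plate simulation
#'
#' @param growth_factor Multiplier on the untreated growth rate (0 = full
#'   growth arrest).
#' @param morph_drift Strength of the progressive intensity drift of the cell
#'   texture (0 = none; drives morphology change).
#' @param apop_max Number of apoptotic-like objects present at the final
#'   frame (ramped up linearly from the first frame).
#' @param viability Terminal survival index of the condition.
#' @return A list effect model.
#' @export
drug_effect <- function(growth_factor = 1, morph_drift = 0, apop_max = 0,
                        viability = 1) {
  list(growth_factor = growth_factor, morph_drift = morph_drift,
       apop_max = apop_max, viability = viability)
}

# A combination inherits the most severe effect of its members on each axis
# unless an explicit override for the combination label exists.
combine_effects <- function(condition, effects) {
  if (!is.null(effects[[condition]])) return(effects[[condition]])
  if (condition == "UNTREATED") return(drug_effect())
  members <- strsplit(condition, "+", fixed = TRUE)[[1]]
  per <- purrr::map(members, function(m) effects[[m]] %||% drug_effect())
  list(growth_factor = min(purrr::map_dbl(per, "growth_factor")),
       morph_drift = max(purrr::map_dbl(per, "morph_drift")),
       apop_max = max(purrr::map_dbl(per, "apop_max")),
       viability = min(purrr::map_dbl(per, "viability")))
}

#' Fixture parameters for whole-plate simulation
#'
#' @param shape Frame size in pixels.
#' @param level,noise_sd Background model (see [make_background()]).
#' @param times_h Frame times in hours.
#' @param n_cells0 Seeded cell count per well at the first frame.
#' @param cell_radius Cell blob radius in pixels.
#' @param cell_contrast Cell brightness offset over background.
#' @param growth_rate Untreated exponential growth rate per hour.
#' @param template Apoptotic-like [object_template()] (scaled to the frame).
#' @param blank_signal,control_signal End-point fluorescence of blank and
#'   untreated wells.
#' @param fmca_noise_sd Multiplicative log-normal noise sd of the end-point
#'   signal.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(shape = c(96L, 96L), level = 0.4, noise_sd = 0.002,
                         times_h = seq(4, 68, by = 4), n_cells0 = 12L,
                         cell_radius = 3L, cell_contrast = 0.25,
                         growth_rate = 0.02,
                         template = object_template(13L, 12L),
                         blank_signal = 100, control_signal = 1100,
                         fmca_noise_sd = 0.05) {
  structure(list(shape = shape, level = level, noise_sd = noise_sd,
                 times_h = times_h, n_cells0 = n_cells0,
                 cell_radius = cell_radius, cell_contrast = cell_contrast,
                 growth_rate = growth_rate, template = template,
                 blank_signal = blank_signal, control_signal = control_signal,
                 fmca_noise_sd = fmca_noise_sd),
            class = "fixture_spec")
}

# Disc-shaped cell blob as an additive template.
cell_template <- function(radius, contrast) {
  n <- 2L * radius + 1L
  d <- sqrt(outer((seq_len(n) - radius - 1L)^2, (seq_len(n) - radius - 1L)^2, `+`))
  (d <= radius) * contrast
}

# Simulate one well's frame series under an effect model.
simulate_well_frames <- function(effect, fixture, seed) {
  sh <- fixture$shape
  t0 <- fixture$times_h[1]
  tmax <- max(fixture$times_h) - t0
  cellt <- cell_template(fixture$cell_radius, fixture$cell_contrast)
  withr::with_seed(seed, {
    g <- fixture$growth_rate * effect$growth_factor
    n_final <- max(fixture$n_cells0,
                   round(fixture$n_cells0 * exp(g * tmax)))
    margin_r <- center_extent(nrow(cellt))
    margin_c <- center_extent(ncol(cellt))
    cell_pos <- cbind(sample((1 + margin_r[1]):(sh[1] - margin_r[2]), n_final, replace = TRUE),
                      sample((1 + margin_c[1]):(sh[2] - margin_c[2]), n_final, replace = TRUE))
    apop_pos <- if (effect$apop_max > 0) {
      random_centers(effect$apop_max, sh, dim(fixture$template))
    } else {
      matrix(integer(0), ncol = 2)
    }
    frame_seeds <- sample.int(.Machine$integer.max - 1L, length(fixture$times_h))
    purrr::map2(fixture$times_h, frame_seeds, function(t, fs) {
      frame <- make_background(sh, fixture$level, fixture$noise_sd, seed = fs)
      n_cells <- min(n_final, max(1L, round(fixture$n_cells0 * exp(g * (t - t0)))))
      drift <- effect$morph_drift * 0.3 * (t - t0) / max(tmax, 1)
      ct <- cellt + (cellt > 0) * drift
      for (i in seq_len(n_cells)) {
        rows <- (cell_pos[i, 1] - margin_r[1]):(cell_pos[i, 1] + margin_r[2])
        cols <- (cell_pos[i, 2] - margin_c[1]):(cell_pos[i, 2] + margin_c[2])
        frame[rows, cols] <- frame[rows, cols] + ct
      }
      n_apop <- round(effect$apop_max * (t - t0) / max(tmax, 1))
      if (n_apop > 0) {
        frame <- plant_objects(frame, fixture$template,
                               apop_pos[seq_len(n_apop), , drop = FALSE])$frame
      }
      pmin(pmax(frame, 0), 1)
    })
  })
}

#' Simulate a full replicate plate set
#'
#' For every non-BLANK well of the layout(s), generates the frame series
#' under the well condition's effect model (combinations inherit the most
#' severe member effect unless overridden), plus an end-point fluorescence
#' table proportional to the terminal viability with multiplicative
#' log-normal noise, and a ground-truth table. Replicate plates share effect
#' models but re-draw all noise.
#'
#' @param layouts `plate_layout` tibble (one or more replicates).
#' @param effects Named list of [drug_effect()] models keyed by drug name
#'   (combination-label keys override the inheritance rule); drugs without an
#'   entry behave as untreated.
#' @param fixture A [fixture_spec()].
#' @param seed Master seed.
#' @return List: `frames` (named list `replicate -> well -> list of frames`),
#'   `fmca` (tibble `replicate_id`, `well`, `signal`), `truth` (tibble per
#'   well: condition, effect parameters), `times_h`.
#' @export
simulate_plate <- function(layouts, effects = list(), fixture = fixture_spec(),
                           seed = 1L) {
  reps <- unique(layouts$replicate_id)
  out_frames <- list()
  fmca <- list()
  truth <- list()
  for (r in reps) {
    lay <- dplyr::filter(layouts, .data$replicate_id == r)
    wells <- dplyr::filter(lay, .data$condition != "BLANK")
    frames <- purrr::map(seq_len(nrow(wells)), function(i) {
      eff <- combine_effects(wells$condition[i], effects)
      simulate_well_frames(eff, fixture,
                           seed = derive_seed(seed, r * 100000L + i))
    })
    names(frames) <- wells$well
    out_frames[[sprintf("R%d", r)]] <- frames
    sig <- withr::with_seed(derive_seed(seed, r * 100000L + 99999L), {
      purrr::map_dbl(seq_len(nrow(lay)), function(i) {
        cond <- lay$condition[i]
        if (cond == "BLANK") {
          fixture$blank_signal * exp(stats::rnorm(1, 0, fixture$fmca_noise_sd / 2))
        } else {
          v <- combine_effects(cond, effects)$viability
          (fixture$blank_signal +
             v * (fixture$control_signal - fixture$blank_signal)) *
            exp(stats::rnorm(1, 0, fixture$fmca_noise_sd))
        }
      })
    })
    fmca[[length(fmca) + 1]] <- tibble::tibble(replicate_id = r, well = lay$well,
                                               signal = sig)
    truth[[length(truth) + 1]] <- dplyr::mutate(
      wells[, c("replicate_id", "well", "condition")],
      purrr::list_rbind(purrr::map(wells$condition, function(cond) {
        tibble::as_tibble(combine_effects(cond, effects))
      }))
    )
  }
  list(frames = out_frames, fmca = purrr::list_rbind(fmca),
       truth = purrr::list_rbind(truth), times_h = fixture$times_h)
}

#' Write a simulated image set to disk
#'
#' Files follow the `{plate}_{well}_{frame:02d}.tif` convention consumed by
#' [read_image_set()].
#'
#' @param frames Named list `replicate -> well -> list of frames` (the
#'   `frames` element of [simulate_plate()]).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_image_set <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (plate in names(frames)) {
    for (well in names(frames[[plate]])) {
      fr <- frames[[plate]][[well]]
      for (i in seq_along(fr)) {
        tiff::writeTIFF(pmin(pmax(fr[[i]], 0), 1),
                        file.path(dir, sprintf("%s_%s_%02d.tif", plate, well, i)))
      }
    }
  }
  invisible(dir)
}
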