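# Shared fixture builders: all synthetic, generated at test time.

cusp9_panel <- function() {
  drug_panel(
    c("Apr", "Min", "Aur", "Cap", "Cel", "Dis", "Itr", "Ser", "Que"),
    c(2.6, 0.44, 0.15, 0.12, 1.6, 0.67, 0.3, 0.5, 3)
  )
}

# Flat background frame with a given level (no noise).
flat_frame <- function(shape = c(64L, 64L), level = 0.4) {
  matrix(level, shape[1], shape[2])
}

# Brute-force valid cross-correlation oracle (independent of filter_response).
brute_force_response <- function(frame, w) {
  nr <- nrow(frame) - nrow(w) + 1L
  nc <- ncol(frame) - ncol(w) + 1L
  y <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      y[i, j] <- sum(w * frame[i:(i + nrow(w) - 1L), j:(j + ncol(w) - 1L)])
    }
  }
  y
}

# Brute-force subset-minimal elements of a family of combinations.
brute_force_antichain <- function(labels) {
  members <- lapply(labels, function(l) sort(strsplit(l, "+", fixed = TRUE)[[1]]))
  minimal <- vapply(seq_along(members), function(i) {
    !any(vapply(seq_along(members), function(j) {
      j != i && length(members[[j]]) < length(members[[i]]) &&
        all(members[[j]] %in% members[[i]])
    }, logical(1)))
  }, logical(1))
  # also drop duplicates dominated by an equal set (labels are unique here)
  sort(labels[minimal])
}

# Random combination family over n_drugs drugs.
random_family <- function(n_drugs, n_combos, seed) {
  withr::with_seed(seed, {
    drugs <- LETTERS[seq_len(n_drugs)]
    labs <- unique(replicate(n_combos, {
      k <- sample(n_drugs, 1)
      paste(sort(sample(drugs, k)), collapse = "+")
    }))
    labs
  })
}

# Gaussian profile cloud around a center.
gauss_cloud <- function(n, center, sd, seed) {
  withr::with_seed(seed, {
    matrix(rnorm(n * length(center), mean = rep(center, each = n), sd = sd),
           nrow = n)
  })
}

# Training set of annotated frames with planted prototype-like objects.
annotated_training_frames <- function(n_images = 8, shape = c(96L, 96L),
                                      template = object_template(13L, 12L),
                                      level = 0.4, counts = NULL, seed = 1) {
  if (is.null(counts)) counts <- rep_len(0:4, n_images)
  frames <- lapply(seq_len(n_images), function(i) {
    f <- make_background(shape, level, seed = seed * 1000 + i)
    if (counts[i] > 0) {
      ctr <- withr::with_seed(seed * 2000 + i,
                              random_centers(counts[i], shape, dim(template)))
      f <- plant_objects(f, template, ctr)$frame
    }
    f
  })
  tibble::tibble(frame = frames, observed = counts[seq_len(n_images)])
}
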