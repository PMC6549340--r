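# Matched filter, the two counting algorithms, and threshold tuning.

test_that("filter coefficients are the prototype minus the background level", {
  s <- matrix(0.4, 9, 8)
  expect_warning(m0 <- build_filter(s, 0.4), "degenerate")
  expect_true(all(m0$w == 0))
  s[5, 4] <- 0.4 + 0.2
  m <- build_filter(s, 0.4)
  expect_equal(sum(m$w != 0), 1)
  expect_equal(m$w[5, 4], 0.2)
  proto <- 0.4 + object_template(33, 32)
  expect_equal(dim(build_filter(proto, 0.4)$w), c(33L, 32L))
  s[1, 1] <- NA
  expect_error(build_filter(s, 0.4), "non-finite")
})

test_that("filter response equals the brute-force correlation oracle", {
  tpl <- object_template(9, 8, ring = 0.3, core = -0.1)
  model <- build_filter(0.4 + tpl, 0.4)
  # pure-background closed form
  f_bg <- flat_frame(c(20, 20), 0.55)
  r_bg <- filter_response(f_bg, model)
  expect_equal(max(abs(r_bg - sum(model$w) * 0.55)), 0, tolerance = 1e-12)
  # seeded fixtures against the double-loop oracle
  for (s in 1:10) {
    f <- make_background(c(64, 64), 0.4, noise_sd = 0.02, seed = s)
    r <- filter_response(f, model)
    expect_lt(max(abs(unclass(r) - brute_force_response(f, model$w))), 1e-9)
  }
  expect_error(filter_response(flat_frame(c(5, 5)), model), "smaller")
})

test_that("the response peaks at a planted prototype and is linear in contrast", {
  tpl <- object_template(9, 8, ring = 0.3, core = -0.1)
  model <- build_filter(0.4 + tpl, 0.4)
  f <- flat_frame(c(100, 100), 0.4)
  ctr <- c(40, 60)
  pl <- plant_objects(f, tpl, rbind(ctr))
  r <- filter_response(pl$frame, model)
  peak <- arrayInd(which.max(r), dim(r))
  # response coordinates are patch top-left: center minus the center extents
  expect_equal(as.integer(peak), ctr - c(4L, 4L))

  f2 <- 0.4 + 2 * (pl$frame - 0.4) # doubled contrast about b
  r2 <- filter_response(f2, model)
  bg <- sum(model$w) * 0.4
  expect_equal(unclass(r2) - bg, 2 * (unclass(r) - bg), tolerance = 1e-9)
})

test_that("taboo counting picks separated peaks and stops below threshold", {
  tpl <- object_template(9, 8, ring = 0.3, core = -0.1)
  model <- build_filter(0.4 + tpl, 0.4)
  f <- flat_frame(c(80, 80), 0.4)
  r0 <- filter_response(f, model)
  expect_equal(taboo_count(r0, max(r0) + 1)$count, 0)

  one <- plant_objects(f, tpl, rbind(c(30, 30)))
  r1 <- filter_response(one$frame, model)
  tau <- (sum(model$w) * 0.4 + max(r1)) / 2
  tb1 <- taboo_count(r1, tau)
  expect_equal(tb1$count, 1)
  expect_equal(as.integer(tb1$centers[1, ]) + c(4L, 4L), c(30L, 30L))

  two <- plant_objects(f, tpl, rbind(c(20, 20), c(55, 60)))
  tb2 <- taboo_count(filter_response(two$frame, model), tau)
  expect_equal(tb2$count, 2)
})

test_that("position counting projects supra-threshold intervals in two passes", {
  r <- structure(matrix(0, 20, 20), class = c("response_map", "matrix", "array"),
                 patch_shape = c(3L, 3L))
  expect_equal(position_count(r, 1), 0)
  r[5:7, 5:7] <- 2
  expect_equal(position_count(r, 1), 1)
  # two blobs sharing columns but disjoint rows: caught by the vertical pass
  r2 <- r
  r2[12:14, 5:7] <- 2
  expect_equal(position_count(r2, 1), 2)
  # cross-check against a connected-component oracle on separated blobs
  withr::with_seed(3, {
    for (i in 1:10) {
      rm <- matrix(0, 40, 40)
      n <- sample(0:4, 1)
      placed <- 0
      guard <- 0
      pos <- matrix(numeric(0), ncol = 2)
      while (placed < n && guard < 100) {
        guard <- guard + 1
        cand <- c(sample(3:37, 1), sample(3:37, 1))
        if (nrow(pos) == 0 || all(abs(pos[, 1] - cand[1]) > 6 | abs(pos[, 2] - cand[2]) > 6)) {
          rm[cand[1] + (-1:1), cand[2] + (-1:1)] <- 2
          pos <- rbind(pos, cand)
          placed <- placed + 1
        }
      }
      rr <- structure(rm, class = c("response_map", "matrix", "array"),
                      patch_shape = c(3L, 3L))
      cc <- max(EBImage::bwlabel(EBImage::Image(rm >= 1)))
      expect_equal(position_count(rr, 1), cc)
    }
  })
})

test_that("frame and well counts run both algorithms and are order independent", {
  tpl <- object_template(9, 8, ring = 0.3, core = -0.1)
  model <- build_filter(0.4 + tpl, 0.4)
  expect_error(frame_count(flat_frame(c(60, 60), 0.4), model),
               class = "combiscreen_not_tuned")
  bg_resp <- sum(model$w) * 0.4
  f <- flat_frame(c(120, 120), 0.4)
  peak <- max(filter_response(plant_objects(f, tpl, rbind(c(30, 30)))$frame, model))
  model <- set_threshold(model, (bg_resp + peak) / 2)

  blank <- frame_count(flat_frame(c(60, 60), 0.4), model)
  expect_equal(c(blank$taboo, blank$position, blank$mean_count), c(0, 0, 0))

  ctr5 <- withr::with_seed(5, random_centers(5, c(120, 120), dim(tpl)))
  five <- plant_objects(f, tpl, ctr5)
  fc <- frame_count(five$frame, model)
  expect_equal(c(fc$taboo, fc$position, fc$mean_count), c(5, 5, 5))

  frames <- lapply(0:3, function(n) {
    ctr <- withr::with_seed(50 + n, random_centers(n, c(120, 120), dim(tpl)))
    plant_objects(f, tpl, ctr)$frame
  })
  wc <- well_counts(frames, model, times_h = c(4, 8, 12, 16))
  expect_equal(wc$mean_count, c(0, 1, 2, 3))
  # permuted processing order yields the permuted rows (frames independent)
  perm <- c(3, 1, 4, 2)
  wc_perm <- well_counts(frames[perm], model, times_h = c(4, 8, 12, 16)[perm])
  expect_equal(wc_perm$mean_count, wc$mean_count[perm])
})

test_that("both counters recover planted counts and agree when objects are separated", {
  tpl <- object_template(9, 8, ring = 0.3, core = -0.1)
  model <- build_filter(0.4 + tpl, 0.4)
  bg_resp <- sum(model$w) * 0.4
  f0 <- flat_frame(c(96, 96), 0.4)
  peak <- max(filter_response(plant_objects(f0, tpl, rbind(c(30, 30)))$frame, model))
  model <- set_threshold(model, (bg_resp + peak) / 2)
  diag_sep <- ceiling(sqrt(sum(dim(tpl)^2))) + 1
  for (s in 1:25) {
    n_true <- s %% 5
    f <- make_background(c(96, 96), 0.4, seed = 600 + s)
    ctr <- withr::with_seed(700 + s,
                            random_centers(n_true, c(96, 96), dim(tpl), sep = diag_sep))
    fr <- plant_objects(f, tpl, ctr)$frame
    fc <- frame_count(fr, model)
    expect_equal(fc$taboo, n_true)
    expect_equal(fc$position, n_true)
    expect_lte(abs(fc$taboo - fc$position), 1)
  }
})

test_that("counting is robust to the exact prototype choice", {
  # four similar prototypes (slightly different sizes), same planted frames
  protos <- list(object_template(13, 12), object_template(15, 14),
                 object_template(13, 14), object_template(15, 12))
  frames <- lapply(1:4, function(s) {
    f <- make_background(c(96, 96), 0.4, seed = 900 + s)
    ctr <- withr::with_seed(950 + s, random_centers(4, c(96, 96), c(15, 14)))
    plant_objects(f, object_template(14, 13), ctr)$frame
  })
  counts <- vapply(protos, function(tpl) {
    model <- build_filter(0.4 + tpl, 0.4)
    bg_resp <- sum(model$w) * 0.4
    peak <- max(filter_response(
      plant_objects(flat_frame(c(96, 96), 0.4), object_template(14, 13),
                    rbind(c(48, 48)))$frame, model))
    model <- set_threshold(model, (bg_resp + peak) / 2)
    mean(vapply(frames, function(f) frame_count(f, model)$mean_count, numeric(1)))
  }, numeric(1))
  expect_lt((max(counts) - min(counts)) / max(mean(counts), 1e-9), 0.10)
})

test_that("threshold tuning finds a zero-loss threshold when one exists", {
  tpl <- object_template(13, 12)
  model <- build_filter(0.4 + tpl, 0.4)
  training <- annotated_training_frames(8, template = tpl, seed = 3)
  tuned <- tune_threshold(training, model, folds = 4, repeats = 2, seed = 11)
  expect_equal(median(tuned$tuning$test_loss), 0)
  expect_equal(nrow(tuned$tuning), 8) # 4 folds x 2 repeats
  # every training frame is counted exactly at the tuned threshold
  losses <- vapply(seq_len(nrow(training)), function(i) {
    abs(frame_count(training$frame[[i]], tuned)$mean_count - training$observed[i])
  }, numeric(1))
  expect_equal(mean(losses), 0)
  # deterministic under the same seed
  tuned2 <- tune_threshold(training, model, folds = 4, repeats = 2, seed = 11)
  expect_equal(tuned2$tau, tuned$tau)
})

test_that("tuning aborts on overfit-level disagreement and too little data", {
  tpl <- object_template(13, 12)
  model <- build_filter(0.4 + tpl, 0.4)
  training <- annotated_training_frames(8, template = tpl, seed = 4)
  # adversarial annotations: alternate wildly conflicting counts so no
  # threshold can reconcile folds (median held-out loss > 5 by construction)
  training$observed <- training$observed + c(0, 25, 0, 25, 0, 25, 0, 25)
  expect_error(tune_threshold(training, model, seed = 2),
               class = "combiscreen_overfit")
  expect_error(tune_threshold(training[1:3, ], model, folds = 4), "at least")
})

test_that("tidy and glance expose the tuning report", {
  tpl <- object_template(13, 12)
  model <- build_filter(0.4 + tpl, 0.4)
  expect_equal(nrow(tidy(model)), 0)
  expect_true(is.na(glance(model)$tau))
  training <- annotated_training_frames(8, template = tpl, seed = 5)
  tuned <- tune_threshold(training, model, seed = 7)
  expect_named(tidy(tuned), c("repeat_id", "fold", "tau_j", "train_loss", "test_loss"))
  expect_equal(glance(tuned)$tau, tuned$tau)
})
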