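# Survival index, higher-order Bliss and scaled Bliss, and resampling
# significance.

test_that("survival index normalizes between blank and control medians", {
  blanks <- c(9, 10, 11)
  controls <- c(100, 110, 120)
  expect_equal(survival_index(110, blanks, controls), 1)
  expect_equal(survival_index(10, blanks, controls), 0)
  expect_equal(survival_index(55, blanks, controls), 0.45)
  expect_equal(survival_index(c(10, 110), blanks, controls), c(0, 1))
  expect_error(survival_index(5, c(1, 2, 3), c(1, 2, 3)), "degenerate")
})

test_that("Bliss and scaled Bliss reproduce the closed-form substitutions", {
  expect_equal(bliss_index(c(0.5, 0.5), 0.25), 0, tolerance = 1e-12)
  expect_equal(bliss_index(c(1, 1), 0), 1, tolerance = 1e-12)
  # order-4 case
  expect_equal(bliss_index(rep(0.9, 4), 0.41), 0.6561 - 0.41, tolerance = 1e-12)
  expect_equal(scaled_bliss(c(0.9, 0.9), 0.41), 0.40 * (1 - 0.41), tolerance = 1e-12)
  expect_equal(scaled_bliss(c(0.5, 0.5), 0.50), -0.25 * (1 - 0.25), tolerance = 1e-12)
  expect_equal(scaled_bliss(c(0.6, 0.5), 0.30), 0, tolerance = 1e-12)
  expect_error(bliss_index(numeric(0), 0.5), "at least 2")
  expect_error(bliss_index(0.5, 0.5), "at least 2")
})

test_that("scaled Bliss is dominated by Bliss and disambiguates equal-B pairs", {
  grid <- seq(0, 1, length.out = 101)
  for (expected in grid) {
    observed <- grid
    B <- expected - observed
    BS <- vapply(observed, function(o) {
      # direct evaluation through the two-survival parameterization
      s1 <- sqrt(expected)
      scaled_bliss(c(s1, s1), o)
    }, numeric(1))
    expect_true(all(abs(BS) <= abs(B) + 1e-12))
    sup <- 1 - pmin(expected, observed)
    # equality only where the suppressing term is 1 - 0 = 1 or B = 0
    eq <- abs(abs(BS) - abs(B)) < 1e-12 & abs(B) > 1e-12
    expect_true(all(pmin(expected, observed)[eq] == 0))
    expect_equal(BS, B * sup, tolerance = 1e-12)
  }
  # same B, different (expected, observed): different B_S
  b1 <- scaled_bliss(c(1, 0.9), 0.6)   # expected .9, observed .6, B = .3
  b2 <- scaled_bliss(c(0.8, 0.5), 0.1) # expected .4, observed .1, B = .3
  expect_equal(bliss_index(c(1, 0.9), 0.6), bliss_index(c(0.8, 0.5), 0.1))
  expect_false(isTRUE(all.equal(b1, b2)))
})

test_that("the order-2 forms match hand-computed pairwise scores", {
  # S_A = 0.8, S_B = 0.7, combo 0.4: expected 0.56, B = 0.16,
  # B_S = 0.16 * (1 - 0.4) = 0.096
  expect_equal(bliss_index(c(0.8, 0.7), 0.4), 0.16, tolerance = 1e-12)
  expect_equal(scaled_bliss(c(0.8, 0.7), 0.4), 0.096, tolerance = 1e-12)
  # antagonism: combo 0.7 > expected 0.56, B = -0.14, B_S = -0.14 * (1 - 0.56)
  expect_equal(scaled_bliss(c(0.8, 0.7), 0.7), -0.14 * 0.44, tolerance = 1e-12)
})

test_that("resampling significance is seeded and detects separation", {
  # Bliss-independent, replicates identical: B_S = 0, p = 1
  res0 <- synergy_significance(list(c(0.5, 0.5, 0.5), c(0.6, 0.6, 0.6)),
                               rep(0.3, 3), n_boot = 500, seed = 1)
  expect_equal(res0$B_S, 0)
  expect_equal(res0$p_value, 1)

  res1 <- synergy_significance(list(c(0.9, 0.85, 0.92), c(0.88, 0.9, 0.86)),
                               c(0.2, 0.25, 0.22), n_boot = 2000, seed = 7)
  res1b <- synergy_significance(list(c(0.9, 0.85, 0.92), c(0.88, 0.9, 0.86)),
                                c(0.2, 0.25, 0.22), n_boot = 2000, seed = 7)
  expect_identical(res1, res1b)

  # strongly separated synthetic synergy: singles ~1, combo ~0, tight noise
  strong <- synergy_significance(
    list(c(1, 0.99, 1.01, 1), c(0.99, 1, 1, 1.01)),
    c(0, 0.01, 0, 0.005), n_boot = 2000, seed = 3)
  expect_lt(strong$p_value, 2 / 2000)
  expect_error(synergy_significance(list(c(1, 1), c(1, 1)), 0.5),
               class = "combiscreen_insufficient_replicates")
})

test_that("plate synergy tables score every combination of the screen", {
  panel <- cusp9_panel()
  spec <- design_spec(panel, 4, replicates = 4, seed = 15)
  layouts <- design_layouts(spec)
  # Bliss-independent world: S(drug) fixed, S(combo) = product of singles
  s_single <- stats::setNames(seq(0.91, 0.99, length.out = 9), panel$name)
  s_of <- function(cond) {
    if (cond == "UNTREATED") return(1)
    prod(s_single[strsplit(cond, "+", fixed = TRUE)[[1]]])
  }
  blank <- 100; control <- 1100
  measurements <- layouts |>
    dplyr::mutate(signal = vapply(condition, function(cond) {
      if (cond == "BLANK") blank else blank + s_of(cond) * (control - blank)
    }, numeric(1))) |>
    dplyr::select(replicate_id, well, signal)
  tab <- plate_synergy_table(measurements, layouts, n_boot = 50, seed = 1)
  expect_equal(nrow(tab), 246)
  expect_equal(unname(table(tab$order)), array(c(36L, 84L, 126L)))
  expect_equal(max(abs(tab$B)), 0, tolerance = 1e-9)
  expect_equal(max(abs(tab$B_S)), 0, tolerance = 1e-9)
  expect_false(any(tab$qc_excluded))

  # independent brute-force recomputation on a random fixture
  withr::with_seed(9, {
    noisy <- layouts |>
      dplyr::mutate(signal = vapply(condition, function(cond) {
        if (cond == "BLANK") blank else
          (blank + s_of(cond) * (control - blank)) * exp(rnorm(1, 0, 0.05))
      }, numeric(1))) |>
      dplyr::select(replicate_id, well, signal)
  })
  tab2 <- plate_synergy_table(noisy, layouts, n_boot = 10, seed = 1)
  # oracle for one combination
  cond <- "Apr+Dis"
  joined <- dplyr::inner_join(noisy, layouts, by = c("replicate_id", "well"))
  s_rep <- function(cc) {
    vapply(1:4, function(r) {
      p <- joined[joined$replicate_id == r, ]
      (p$signal[p$condition == cc] - median(p$signal[p$condition == "BLANK"])) /
        (median(p$signal[p$condition == "UNTREATED"]) -
           median(p$signal[p$condition == "BLANK"]))
    }, numeric(1))
  }
  expected_o <- mean(s_rep("Apr")) * mean(s_rep("Dis"))
  observed_o <- mean(s_rep(cond))
  row <- tab2[tab2$condition == cond, ]
  expect_equal(row$expected, expected_o, tolerance = 1e-12)
  expect_equal(row$observed, observed_o, tolerance = 1e-12)
  expect_equal(row$B, expected_o - observed_o, tolerance = 1e-12)

  # missing single-drug reference aborts with the drug named
  broken <- dplyr::filter(layouts, condition != "Dis")
  expect_error(
    plate_synergy_table(dplyr::semi_join(noisy, broken, by = c("replicate_id", "well")),
                        broken, n_boot = 10),
    class = "combiscreen_missing_reference")
})
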