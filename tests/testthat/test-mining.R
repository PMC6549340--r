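# Profile fusion, multilevel K-means, K selection, and the non-redundant
# subset search.

test_that("fusion stacks four std-normalized blocks of equal length", {
  x <- fuse_profiles(dC = seq(0, 2, length.out = 17), dM = rep(1:17) / 10,
                     counts = rep(0, 17), viability = 0.8)
  expect_equal(length(x), 68) # N = 4n with n = 17 frames
  # constant blocks (counts, viability) pass through unscaled
  expect_equal(as.numeric(x[35:51]), rep(0, 17))
  expect_equal(as.numeric(x[52:68]), rep(0.8, 17))
  # scale invariance of non-constant blocks
  x10 <- fuse_profiles(dC = 10 * seq(0, 2, length.out = 17), dM = rep(1:17) / 10,
                       counts = rep(0, 17), viability = 0.8)
  expect_equal(as.numeric(x10[1:17]), as.numeric(x[1:17]), tolerance = 1e-12)
  expect_error(fuse_profiles(1:5, 1:4, 1:5, 1), "share one length")
})

test_that("k-means partition matches closed forms and an exhaustive oracle", {
  X <- gauss_cloud(12, c(0, 0, 0), 1, seed = 5)
  k1 <- kmeans_partition(X, 1)
  expect_equal(k1$sse, sum(scale(X, scale = FALSE)^2), tolerance = 1e-9)
  kn <- kmeans_partition(X, nrow(X), repeats = 3, seed = 2)
  expect_equal(kn$sse, 0, tolerance = 1e-9)

  # 8 points, K = 2: exhaustive best 2-coloring oracle
  X8 <- gauss_cloud(8, c(0, 0), 1.5, seed = 11)
  best <- Inf
  for (code in 1:(2^7 - 1)) { # fix point 1 in cluster 1, enumerate the rest
    assign <- c(1L, as.integer(intToBits(code)[1:7]) + 1L)
    sse <- sum(vapply(1:2, function(k) {
      sub <- X8[assign == k, , drop = FALSE]
      if (nrow(sub) == 0) 0 else sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
    best <- min(best, sse)
  }
  k2 <- kmeans_partition(X8, 2, repeats = 20, seed = 3)
  expect_equal(k2$sse, best, tolerance = 1e-9)
  expect_error(kmeans_partition(X8, 9), "exceeds")
})

test_that("the 20% SSE-drop rule selects K as specified", {
  same <- matrix(1, 10, 4)
  expect_equal(select_k(same, seed = 1)$K, 1)

  # two tight, well-separated clusters: the K=1 -> 2 transition drops > 20%
  X2 <- rbind(gauss_cloud(15, c(0, 0, 0), 0.1, seed = 7),
              gauss_cloud(15, c(10, 10, 10), 0.1, seed = 8))
  sel2 <- select_k(X2, repeats = 5, seed = 4)
  expect_equal(sel2$K, 2)
  # verified by direct SSE computation
  e1 <- sum(scale(X2, scale = FALSE)^2)
  e2 <- kmeans_partition(X2, 2, repeats = 5, seed = 9)$sse
  expect_lt((e2 - e1) / e1 * 100, -20)

  # a single isotropic cloud: consecutive drops stay milder than the rule
  # (spherical SSE declines gently in K), calibrated by its own SSE trace
  X1 <- gauss_cloud(60, rep(0, 8), 1, seed = 12)
  sel1 <- select_k(X1, repeats = 5, seed = 5)
  trace_drops <- sel1$drops[!is.na(sel1$drops)]
  if (all(trace_drops > -20)) expect_equal(sel1$K, 1)
})

test_that("multilevel clustering recovers a planted 2x2 hierarchy deterministically", {
  centers <- list(c(0, 0), c(3, 0), c(40, 40), c(43, 40))
  X <- do.call(rbind, purrr::imap(centers, function(ctr, i) {
    gauss_cloud(10, rep(ctr, each = 4), 0.25, seed = 20 + i)
  }))
  rownames(X) <- paste0("c", seq_len(nrow(X)))
  true_label <- rep(1:4, each = 10)
  tree <- multilevel_cluster(X, max_depth = 2, min_size = 8, repeats = 10, seed = 6)
  expect_equal(length(tree$children), 2)                      # 2 main groups
  expect_equal(vapply(tree$children, function(ch) length(ch$children), integer(1)),
               c(2L, 2L))                                     # 2 subgroups each
  leaves <- tidy(tree)
  expect_equal(nrow(leaves), 40)
  # leaf assignment agrees with the planted labels
  recovered <- as.integer(factor(leaves$node[match(rownames(X), leaves$condition)]))
  agree <- mclust::adjustedRandIndex(recovered, true_label)
  expect_gte(agree, 0.9)
  # determinism
  tree2 <- multilevel_cluster(X, max_depth = 2, min_size = 8, repeats = 10, seed = 6)
  expect_identical(tree, tree2)

  # homogeneous data: single leaf
  X0 <- gauss_cloud(20, c(0, 0, 0), 1, seed = 30)
  rownames(X0) <- paste0("h", 1:20)
  t0 <- multilevel_cluster(X0, seed = 2)
  if (t0$K == 1) expect_equal(length(t0$children), 0)
})

test_that("SSE is non-increasing in K with best-of-R restarts", {
  X <- rbind(gauss_cloud(20, c(0, 0, 0, 0), 1, seed = 40),
             gauss_cloud(20, c(4, 0, 0, 0), 1, seed = 41))
  sse <- vapply(1:6, function(k) kmeans_partition(X, k, repeats = 8, seed = k)$sse,
                numeric(1))
  expect_true(all(diff(sse) <= 1e-9))
})

test_that("nonredundant_subset returns exactly the subset-minimal combinations", {
  expect_identical(nonredundant_subset(c("X", "X+Y", "W+X+Z")), "X")
  expect_setequal(nonredundant_subset(c("X", "X+Y", "Y+Z")), c("X", "Y+Z"))
  # a drug plus every combination containing it collapses to the drug
  fam <- c("Dis", "Apr+Dis", "Dis+Min", "Apr+Dis+Min", "Cel+Dis+Min+Que")
  expect_identical(nonredundant_subset(fam), "Dis")
  # order independence
  expect_identical(nonredundant_subset(rev(fam)), "Dis")

  # brute-force antichain oracle over random families
  for (s in 1:30) {
    fam <- random_family(n_drugs = sample(3:9, 1), n_combos = sample(5:25, 1),
                         seed = 100 + s)
    got <- nonredundant_subset(fam)
    expect_identical(sort(got), brute_force_antichain(fam))
    # antichain: no representative contains another
    mem <- lapply(got, function(l) strsplit(l, "+", fixed = TRUE)[[1]])
    for (i in seq_along(mem)) for (j in seq_along(mem)) {
      if (i != j) expect_false(all(mem[[i]] %in% mem[[j]]))
    }
    # coverage: every member is a superset of some representative
    for (l in fam) {
      mm <- strsplit(l, "+", fixed = TRUE)[[1]]
      expect_true(any(vapply(mem, function(r) all(r %in% mm), logical(1))))
    }
  }
})

test_that("group reports average member profiles in original units", {
  profiles <- tibble::tibble(
    condition = c("Dis", "Apr+Dis", "Apr", "Min", "Apr+Min"),
    dC = c(list(c(0, 0.1, 0.1)), list(c(0, 0.12, 0.08)),
           list(c(0, 1, 2)), list(c(0, 1.1, 2.1)), list(c(0, 0.9, 1.9))),
    dM = c(list(c(0, 2, 3)), list(c(0, 2.1, 3.2)),
           list(c(0, 0.2, 0.4)), list(c(0, 0.25, 0.35)), list(c(0, 0.2, 0.42))),
    counts = c(list(c(0, 5, 9)), list(c(0, 6, 10)),
               list(c(0, 0, 1)), list(c(0, 0, 0)), list(c(0, 1, 0))),
    viability = c(0.1, 0.08, 0.95, 0.97, 0.96)
  )
  res <- mine_responses(profiles, max_depth = 1, min_size = 2, repeats = 5, seed = 3)
  rep_tbl <- res$report
  # two groups: the Dis-driven one is represented by Dis alone
  leaf_reps <- rep_tbl$representatives[rep_tbl$is_leaf]
  expect_true(any(vapply(leaf_reps, function(r) identical(r, "Dis"), logical(1))))
  # averages equal independent recomputation
  dis_leaf <- which(rep_tbl$is_leaf &
                      vapply(rep_tbl$members, function(m) "Dis" %in% m, logical(1)))[1]
  members <- rep_tbl$members[[dis_leaf]]
  oracle <- rowMeans(do.call(cbind, profiles$dC[match(members, profiles$condition)]))
  expect_equal(rep_tbl$avg_dC[[dis_leaf]], oracle)
  # untreated-like group: near-zero counts, viability near 1
  other <- which(rep_tbl$is_leaf)[which(rep_tbl$is_leaf) != dis_leaf][1]
  ot <- setdiff(which(rep_tbl$is_leaf), dis_leaf)[1]
  expect_gt(rep_tbl$avg_viability[ot], 0.9)
  expect_lt(max(rep_tbl$avg_counts[[ot]]), 1.5)
  # leaf with one member reports that member's own profile
  single <- mine_responses(profiles[1:2, ], max_depth = 1, min_size = 2,
                           repeats = 5, seed = 3)
  root <- single$report[single$report$node == "root", ]
  expect_equal(root$n_members, 2)
})
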