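# Fusion of the four per-condition readouts (confluence change, morphology
# change, object counts, end-point viability) into one profile vector, and
# top-down multilevel K-means discovery of prototypical response groups, each
# summarized by its smallest non-redundant representative combination set.

#' Fuse the four response readouts of one condition
#'
#' The scalar viability is first expanded to a constant vector matching the
#' temporal readouts, then each of the four blocks is normalized by its own
#' standard deviation (blocks with zero spread, e.g. the constant viability
#' block, pass through unscaled) and the blocks are concatenated in the fixed
#' order confluence change, morphology change, object counts, viability into
#' a vector of length `4 * n`.
#'
#' @param dC,dM,counts Numeric temporal vectors of common length `n`.
#' @param viability Scalar end-point survival index.
#' @return Numeric vector of length `4n`, with the raw blocks attached as
#'   attribute `"blocks"`.
#' @export
fuse_profiles <- function(dC, dM, counts, viability) {
  n <- length(dC)
  if (length(dM) != n || length(counts) != n) {
    rlang::abort("temporal blocks must share one length")
  }
  if (length(viability) != 1 || !is.finite(viability)) {
    rlang::abort("`viability` must be a finite scalar")
  }
  blocks <- list(dC = as.numeric(dC), dM = as.numeric(dM),
                 counts = as.numeric(counts), viability = rep(viability, n))
  if (!all(purrr::map_lgl(blocks, function(b) all(is.finite(b))))) {
    rlang::abort("profile blocks contain non-finite values")
  }
  x <- unlist(purrr::map(blocks, function(b) {
    s <- stats::sd(b)
    b / (if (is.na(s) || s == 0) 1 else s)
  }), use.names = FALSE)
  structure(x, blocks = blocks)
}

# Stack fused profiles of many conditions into a matrix (rows = conditions).
profile_matrix <- function(profiles) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  do.call(rbind, purrr::map(profiles, as.numeric))
}

# K-means++ seeding: first center uniform, then each next center drawn with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (k in seq_len(K)[-1]) {
    if (all(d2 == 0)) {
      centers[k] <- sample.int(n, 1)
    } else {
      centers[k] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums((X - matrix(X[centers[k], ], n, ncol(X), byrow = TRUE))^2))
  }
  X[centers, , drop = FALSE]
}

#' Best-of-R K-means partition
#'
#' Runs Lloyd's algorithm from `repeats` independent K-means++
#' initializations and keeps the run with the smallest within-cluster sum of
#' squared errors (SSE).
#'
#' @param X Numeric matrix, one profile per row.
#' @param K Number of clusters (`K <= nrow(X)`).
#' @param repeats Independent restarts (default 10).
#' @param seed Seed; restart `r` uses stream `seed + r`.
#' @return List: `cluster` (assignments), `centers`, `sse` (best run),
#'   `sse_runs` (all runs).
#' @export
kmeans_partition <- function(X, K, repeats = 10L, seed = 1L) {
  n <- nrow(X)
  if (K > n) rlang::abort("K exceeds the number of profiles")
  if (K == 1) {
    ctr <- matrix(colMeans(X), 1)
    sse <- sum((X - ctr[rep(1, n), , drop = FALSE])^2)
    return(list(cluster = rep(1L, n), centers = ctr, sse = sse, sse_runs = sse))
  }
  ux <- unique(X)
  if (nrow(ux) <= K) {
    # at most K distinct profiles: the zero-SSE partition is exact
    key <- function(m) apply(m, 1, paste, collapse = "\r")
    cl <- match(key(X), key(ux))
    return(list(cluster = cl, centers = ux, sse = 0, sse_runs = 0))
  }
  runs <- purrr::map(seq_len(repeats), function(r) {
    withr::with_seed(derive_seed(seed, r), {
      init <- kmeanspp_init(X, K)
      # stats::kmeans requires distinct initial centers; K-means++ can draw
      # duplicates when the data has repeated rows
      if (anyDuplicated(init)) init <- ux[sample.int(nrow(ux), K), , drop = FALSE]
      km <- suppressWarnings(stats::kmeans(X, centers = init, iter.max = 100L,
                                           algorithm = "Lloyd"))
      list(cluster = km$cluster, centers = km$centers, sse = km$tot.withinss)
    })
  })
  sse_runs <- purrr::map_dbl(runs, "sse")
  best <- runs[[which.min(sse_runs)]]
  c(best[c("cluster", "centers")], list(sse = best$sse, sse_runs = sse_runs))
}

#' Select the number of clusters by the relative SSE-drop rule
#'
#' Computes the best-of-`repeats` SSE for each candidate `K` and the relative
#' change `(E_K - E_{K-1}) / E_{K-1} * 100` between consecutive values. The
#' selected `K` is the smallest whose transition drop exceeds `drop_pct`
#' percent; when no transition drops that much, `K = 1`. A perfect fit
#' (`E_{K-1} = 0`) stops the scan and returns `K - 1`.
#'
#' @inheritParams kmeans_partition
#' @param K_s Candidate cluster counts (default `1:10`), truncated to
#'   `nrow(X)`.
#' @param drop_pct Required relative SSE drop in percent (default 20).
#' @return List: `K` (selected), `sse` (per-candidate best SSE), `drops`
#'   (relative changes, `NA` for K = 1).
#' @export
select_k <- function(X, K_s = 1:10, repeats = 10L, drop_pct = 20, seed = 1L) {
  K_s <- sort(unique(K_s[K_s <= nrow(X)]))
  sse <- rep(NA_real_, length(K_s))
  drops <- rep(NA_real_, length(K_s))
  selected <- 1L
  for (i in seq_along(K_s)) {
    if (i > 1 && sse[i - 1] == 0) { selected <- K_s[i - 1]; break } # perfect fit
    sse[i] <- kmeans_partition(X, K_s[i], repeats = repeats,
                               seed = derive_seed(seed, 1000L * K_s[i]))$sse
    if (i > 1) {
      drops[i] <- (sse[i] - sse[i - 1]) / sse[i - 1] * 100
      if (drops[i] <= -drop_pct) { selected <- K_s[i]; break }
    }
  }
  list(K = selected, sse = sse, drops = drops, K_s = K_s)
}

#' Top-down multilevel K-means clustering of fused profiles
#'
#' Applies [select_k()] plus [kmeans_partition()] at the root, then recurses
#' into each child cluster until the drop rule selects one cluster, a cluster
#' falls below `min_size` members, or `max_depth` is reached. Node centroids
#' are the prototypical response profiles of their groups.
#'
#' @param X Numeric matrix of fused profiles, rownames = condition labels.
#' @param max_depth Maximum recursion depth (default 2: main groups with one
#'   level of subgroups).
#' @param min_size Do not split groups smaller than this (default 8).
#' @param K_s,repeats,drop_pct,seed Passed to the per-node K selection.
#' @return A `cluster_tree`: nested list of nodes with `id`, `depth`,
#'   `members`, `centroid`, `K`, `sse`, `drops`, `representatives`
#'   (non-redundant combination set of the node), `children`.
#' @export
multilevel_cluster <- function(X, max_depth = 2L, min_size = 8L, K_s = 1:10,
                               repeats = 10L, drop_pct = 20, seed = 1L) {
  if (nrow(X) < 2) rlang::abort("need at least 2 profiles")
  if (is.null(rownames(X))) rownames(X) <- paste0("cond", seq_len(nrow(X)))
  build <- function(rows, depth, id) {
    sub <- X[rows, , drop = FALSE]
    node <- list(id = id, depth = depth, members = rows,
                 centroid = colMeans(sub), K = 1L, sse = NA_real_,
                 drops = NULL,
                 representatives = nonredundant_subset(rows),
                 children = list())
    if (depth >= max_depth || length(rows) < max(2L, min_size)) return(node)
    ks <- select_k(sub, K_s = K_s, repeats = repeats, drop_pct = drop_pct,
                   seed = derive_seed(seed, depth * 7919L + length(rows)))
    node$sse <- ks$sse
    node$drops <- ks$drops
    if (ks$K <= 1L) return(node)
    part <- kmeans_partition(sub, ks$K, repeats = repeats,
                             seed = derive_seed(seed, depth * 7919L + length(rows) + 1L))
    node$K <- ks$K
    # deterministic child order: by first member position
    ord <- order(purrr::map_int(seq_len(ks$K), function(k) min(which(part$cluster == k))))
    node$children <- purrr::imap(ord, function(k, pos) {
      build(rows[part$cluster == k], depth + 1L, paste0(id, ".", pos))
    })
    node
  }
  structure(build(rownames(X), 0L, "root"), class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  walk <- function(node, indent) {
    cat(sprintf("%s%s: %d member(s), representatives: %s\n",
                strrep("  ", indent), node$id, length(node$members),
                paste(node$representatives, collapse = ", ")))
    purrr::walk(node$children, walk, indent = indent + 1)
  }
  walk(x, 0)
  invisible(x)
}

#' Smallest non-redundant representative set of a combination group
#'
#' Iteratively takes the lowest-order remaining combination (lexicographic
#' tie-break), adds it to the representative set, and removes every remaining
#' combination that contains it as a subset. The result is exactly the
#' subset-minimal combinations of the group (an antichain): a group driven by
#' one drug collapses to that single drug.
#'
#' @param group Character vector of combination labels (members joined by
#'   `+`), or a list of member-name vectors.
#' @return Character vector of representative combination labels, ordered as
#'   selected (ascending order, then lexicographic).
#' @export
nonredundant_subset <- function(group) {
  if (length(group) == 0) rlang::abort("empty group")
  labels <- if (is.list(group)) vapply(group, combo_label, "") else as.character(group)
  members <- purrr::map(labels, function(l) sort(strsplit(l, "+", fixed = TRUE)[[1]]))
  ord <- order(lengths(members), labels)
  labels <- labels[ord]
  members <- members[ord]
  reps <- character(0)
  while (length(members) > 0) {
    pick <- members[[1]]
    reps <- c(reps, labels[1])
    keep <- !purrr::map_lgl(members, function(m) all(pick %in% m))
    members <- members[keep]
    labels <- labels[keep]
  }
  reps
}

#' Per-group report of a cluster tree
#'
#' @param tree A [multilevel_cluster()] result.
#' @param raw_blocks Optional named list (by condition) of the raw (pre-
#'   normalization) block lists attached by [fuse_profiles()]; when supplied,
#'   per-node average response blocks are reported in original units.
#' @return Tibble, one row per tree node: `node`, `depth`, `n_members`,
#'   `members` and `representatives` (list columns), `is_leaf`, and (with
#'   `raw_blocks`) list columns `avg_dC`, `avg_dM`, `avg_counts`,
#'   `avg_viability`.
#' @export
group_report <- function(tree, raw_blocks = NULL) {
  rows <- list()
  walk <- function(node) {
    # precompute: the `node` column would otherwise mask the list inside tibble()
    vals <- list(id = node$id, depth = node$depth,
                 n = length(node$members), members = node$members,
                 reps = node$representatives,
                 leaf = length(node$children) == 0)
    row <- tibble::tibble(
      node = vals$id, depth = vals$depth, n_members = vals$n,
      members = list(vals$members), representatives = list(vals$reps),
      is_leaf = vals$leaf
    )
    if (!is.null(raw_blocks)) {
      bl <- raw_blocks[node$members]
      avg <- function(name) list(rowMeans(do.call(cbind, purrr::map(bl, name))))
      row$avg_dC <- avg("dC"); row$avg_dM <- avg("dM")
      row$avg_counts <- avg("counts")
      row$avg_viability <- mean(purrr::map_dbl(bl, function(b) b$viability[1]))
    }
    rows[[length(rows) + 1]] <<- row
    purrr::walk(node$children, walk)
  }
  walk(tree)
  purrr::list_rbind(rows)
}

#' Mine fused response profiles end to end
#'
#' Convenience wrapper: fuses the per-condition readouts of a profile table,
#' clusters them with [multilevel_cluster()], and returns the tree plus the
#' group report.
#'
#' @param profiles Tibble with columns `condition`, `dC`, `dM`, `counts`
#'   (list columns of equal-length numeric vectors) and scalar `viability`.
#' @param ... Passed to [multilevel_cluster()].
#' @return List: `tree` (`cluster_tree`), `report` ([group_report()] tibble),
#'   `X` (fused profile matrix).
#' @export
mine_responses <- function(profiles, ...) {
  fused <- purrr::pmap(profiles[, c("condition", "dC", "dM", "counts", "viability")],
                       function(condition, dC, dM, counts, viability) {
                         fuse_profiles(dC, dM, counts, viability)
                       })
  names(fused) <- profiles$condition
  X <- profile_matrix(fused)
  tree <- multilevel_cluster(X, ...)
  raw <- purrr::map(fused, attr, "blocks")
  list(tree = tree, report = group_report(tree, raw_blocks = raw), X = X)
}
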