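#' Randomly partition a streamline pool into subsets
#'
#' Uniformly random disjoint cover of the pool: a random permutation chunked
#' into consecutive blocks of `subset_size` (the last block takes the
#' remainder), reproducible under `seed`.
#'
#' @param n_pool Pool size (number of pooled streamlines).
#' @param subset_size Target subset size (default 10000).
#' @param seed Integer seed.
#' @return List of integer index vectors; disjoint, union = `1:n_pool`.
#' @export
partition_pool <- function(n_pool, subset_size = 10000L, seed = 1L) {
  if (n_pool < 1) stop("pool must be non-empty", call. = FALSE)
  if (subset_size < 1) stop("subset_size must be >= 1", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n_pool)
  starts <- seq(1, n_pool, by = subset_size)
  lapply(starts, function(s) perm[s:min(s + subset_size - 1, n_pool)])
}

# Flip-aligned mean streamline of a cluster: points of each member are
# reversed if that reduces distance to the running reference (the first
# member), then averaged.
cluster_representative <- function(streamlines, idx) {
  ref <- streamlines[[idx[1]]]
  np <- nrow(ref)
  acc <- matrix(0, np, 3)
  for (i in idx) {
    p <- streamlines[[i]]
    d_fwd <- sum((p - ref)^2)
    d_rev <- sum((p[rev(seq_len(np)), , drop = FALSE] - ref)^2)
    if (d_rev < d_fwd) p <- p[rev(seq_len(np)), , drop = FALSE]
    acc <- acc + p
  }
  acc / length(idx)
}

#' Match cluster labels across two clusterings
#'
#' Finds the one-to-one label mapping between two k-cluster solutions that
#' minimizes the total flip-invariant distance between cluster
#' representatives (the flip-aligned mean resampled streamline per cluster),
#' solved as an optimal assignment.
#'
#' @param ref_reps,other_reps Lists of k representative streamlines
#'   (`n_points` x 3 matrices), indexed by cluster label.
#' @return Integer vector `m` of length k: `m[j]` is the reference label
#'   assigned to label `j` of the other clustering.
#' @export
match_labels <- function(ref_reps, other_reps) {
  k <- length(ref_reps)
  if (length(other_reps) != k) {
    stop("clusterings must have the same number of clusters", call. = FALSE)
  }
  cost <- matrix(0, k, k)
  for (j in seq_len(k)) for (r in seq_len(k)) {
    cost[j, r] <- streamline_distance(other_reps[[j]], ref_reps[[r]])
  }
  solve_assignment(cost)
}

#' Consensus segmentation over repeated clusterings
#'
#' Given r repetition label vectors in a common label space, assigns each
#' streamline its modal label (ties broken by the lowest label) and a
#' stability score: the fraction of repetitions agreeing with the consensus
#' label.
#'
#' @param assignments Integer matrix, streamlines x repetitions, labels in a
#'   common space (after [match_labels()]).
#' @return List of class `consensus_segmentation`: `labels`, `stability`
#'   (both length n), `n_repetitions`.
#' @export
consensus_labels <- function(assignments) {
  assignments <- as.matrix(assignments)
  r <- ncol(assignments)
  if (r == 0) stop("need at least one repetition", call. = FALSE)
  n <- nrow(assignments)
  labels <- integer(n); stability <- numeric(n)
  for (i in seq_len(n)) {
    tab <- table(assignments[i, ])
    best <- max(tab)
    # ties -> lowest label (names are sorted numerically-as-character; sort keys)
    cand <- as.integer(names(tab)[tab == best])
    labels[i] <- min(cand)
    stability[i] <- best / r
  }
  structure(list(labels = labels, stability = stability, n_repetitions = r),
            class = "consensus_segmentation")
}

#' Extract a tract from a consensus segmentation
#'
#' Returns the indices of streamlines whose consensus label belongs to the
#' tract's label set and whose stability meets the pruning threshold. An
#' empty result is returned with a warning (tracts can drop out, mirroring
#' per-tract exclusions in real cohorts).
#'
#' @param consensus A `consensus_segmentation`.
#' @param label_set Integer labels defining the tract.
#' @param stability_min Pruning threshold in `[0, 1]` (default 0.5).
#' @return Integer vector of streamline indices.
#' @export
extract_tract <- function(consensus, label_set, stability_min = 0.5) {
  stopifnot(inherits(consensus, "consensus_segmentation"))
  keep <- which(consensus$labels %in% label_set &
                consensus$stability >= stability_min)
  if (length(keep) == 0) {
    warning("tract with labels {", paste(label_set, collapse = ","),
            "} is empty after pruning", call. = FALSE)
  }
  keep
}

#' Multi-subject consensus bundle clustering
#'
#' The full clustering stage: resample all pooled streamlines to `n_points`,
#' then repeat `repetitions` times — randomly partition the pool into
#' subsets of at most `subset_size`, Ward-cluster each subset into `k`
#' clusters on flip-invariant streamline distances, and map every subset's
#' labels into a global label space by optimally matching cluster
#' representatives. The global reference is subset 1 of repetition 1. The
#' per-streamline modal label over repetitions and its agreement fraction
#' form the consensus segmentation.
#'
#' @param streamlines List of streamline point matrices (any point counts).
#' @param k Clusters per subset.
#' @param subset_size Maximum subset size.
#' @param repetitions Number of repeated random partitions.
#' @param n_points Resampling point count (default 25).
#' @param seed Integer seed controlling all partitions.
#' @return A `consensus_segmentation` with additional fields `resampled`
#'   (the resampled streamlines) and `reference_reps` (the global reference
#'   cluster representatives).
#' @export
cluster_bundles <- function(streamlines, k, subset_size = 10000L,
                            repetitions = 100L, n_points = 25L, seed = 1L) {
  n <- length(streamlines)
  if (n < k) stop("fewer streamlines than clusters", call. = FALSE)
  res <- lapply(streamlines, resample_streamline, n = n_points)
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 1, repetitions)
  assignments <- matrix(NA_integer_, n, repetitions)
  ref_reps <- NULL
  for (r in seq_len(repetitions)) {
    subsets <- partition_pool(n, subset_size, seed = rep_seeds[r])
    for (s in seq_along(subsets)) {
      idx <- subsets[[s]]
      kk <- min(k, length(idx))
      D <- streamline_distance_matrix(res[idx])
      cl <- ward_cluster(D, kk)
      reps <- lapply(seq_len(kk), function(lab) {
        cluster_representative(res, idx[cl$labels == lab])
      })
      if (is.null(ref_reps)) {
        ref_reps <- reps
        assignments[idx, r] <- cl$labels
      } else {
        if (kk < length(ref_reps)) {
          # undersized trailing subset: pad cost by matching available only
          m <- match_subset(reps, ref_reps)
        } else {
          m <- match_labels(ref_reps, reps)
        }
        assignments[idx, r] <- m[cl$labels]
      }
    }
  }
  out <- consensus_labels(assignments)
  out$resampled <- res
  out$reference_reps <- ref_reps
  out
}

# Rectangular matching (fewer clusters than reference labels): pad the cost
# matrix with zero-cost dummy rows and keep the real rows' assignment.
match_subset <- function(reps, ref_reps) {
  k_ref <- length(ref_reps); k <- length(reps)
  cost <- matrix(0, k_ref, k_ref)
  for (j in seq_len(k)) for (r in seq_len(k_ref)) {
    cost[j, r] <- streamline_distance(reps[[j]], ref_reps[[r]])
  }
  solve_assignment(cost)[seq_len(k)]
}
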