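#' Ward hierarchical clustering on a precomputed distance matrix
#'
#' Agglomerative clustering with the Ward minimum-variance criterion,
#' repeatedly merging the pair of clusters whose merge least increases the
#' total within-cluster variance, treating the supplied distances as if
#' Euclidean (the standard accommodation for streamline distances). The
#' merge cost between clusters A and B is
#' `nA*nB/(nA+nB) * |centroid_A - centroid_B|^2`, maintained by the
#' Lance-Williams recursion; exact cost ties are broken by the lowest
#' active-cluster index pair, so the result is fully deterministic.
#'
#' @param d Symmetric numeric matrix with zero diagonal (e.g. from
#'   [streamline_distance_matrix()]).
#' @param k Number of clusters to cut at, `1 <= k <= n`.
#' @return List of class `ward_clustering`: `labels` (integer vector in
#'   `1..k`; clusters numbered by their smallest member index), `k`, `merge`
#'   (hclust-style merge matrix) and `height` (merge costs, length `n-1`).
#' @export
ward_cluster <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (k < 1 || k > n) stop("k must be in 1..n", call. = FALSE)
  if (n == 1) {
    return(structure(list(labels = 1L, k = 1L,
                          merge = matrix(integer(0), 0, 2),
                          height = numeric(0)),
                     class = "ward_clustering"))
  }
  fit <- .ward_merge_cpp(d)
  labels <- cut_merges(fit$merge, n, k)
  structure(list(labels = labels, k = as.integer(k),
                 merge = fit$merge, height = fit$height),
            class = "ward_clustering")
}

# Cut an hclust-style merge matrix at k clusters; clusters are numbered
# 1..k in order of their smallest member index (deterministic labeling).
cut_merges <- function(merge, n, k) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  step_root <- integer(nrow(merge))
  n_steps <- n - k
  if (n_steps > 0) {
    for (s in seq_len(n_steps)) {
      a <- merge[s, 1]; b <- merge[s, 2]
      ra <- if (a < 0) find(-a) else find(step_root[a])
      rb <- if (b < 0) find(-b) else find(step_root[b])
      root <- min(ra, rb)
      parent[ra] <- root; parent[rb] <- root
      step_root[s] <- root
    }
  } else if (nrow(merge) > 0) {
    for (s in seq_len(nrow(merge))) step_root[s] <- NA_integer_
  }
  roots <- vapply(seq_len(n), find, 0L)
  labels <- match(roots, sort(unique(roots)))
  as.integer(labels)
}
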