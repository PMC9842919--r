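# Independent brute-force oracles used across the suite.

# Naive Ward agglomerator: at every step recompute, from the ORIGINAL
# squared distance matrix, the merge cost between every pair of current
# clusters using the as-if-Euclidean centroid identity
#   ||cA - cB||^2 = mean cross d^2 - W_A/2 - W_B/2,
# with W_X the mean within-cluster squared distance (including self pairs),
# and merge the cheapest pair (ties: lowest smallest-member indices).
naive_ward <- function(d) {
  d2 <- d^2
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  ids <- -(seq_len(n))
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  cost_pair <- function(A, B) {
    na <- length(A); nb <- length(B)
    cross <- mean(d2[A, B, drop = FALSE])
    wa <- sum(d2[A, A, drop = FALSE]) / na^2
    wb <- sum(d2[B, B, drop = FALSE]) / nb^2
    (na * nb / (na + nb)) * (cross - wa / 2 - wb / 2)
  }
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- 0L; bj <- 0L
    m <- length(clusters)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      c <- cost_pair(clusters[[i]], clusters[[j]])
      if (c < best - 1e-12) { best <- c; bi <- i; bj <- j }
    }
    merge[step, ] <- c(ids[bi], ids[bj])
    height[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    ids[bi] <- step
    ids <- ids[-bj]
  }
  list(merge = merge, height = height)
}

# Canonical form of a merge sequence: the sorted leaf sets merged at each
# step, so representations with different cluster bookkeeping compare equal.
merge_leaf_sets <- function(merge, n) {
  sets <- vector("list", nrow(merge))
  leaves <- function(x) {
    if (x < 0) -x else sets[[x]]
  }
  for (s in seq_len(nrow(merge))) {
    sets[[s]] <- sort(c(leaves(merge[s, 1]), leaves(merge[s, 2])))
  }
  sets
}

# Brute-force maximum-cardinality ICV matching (<= ~8 per side).
brute_force_matching <- function(icv_men, icv_women, tol) {
  best <- 0L
  recurse <- function(i, used_w, count) {
    if (i > length(icv_men)) { best <<- max(best, count); return() }
    # prune: even pairing all remaining men cannot beat best
    if (count + (length(icv_men) - i + 1) <= best) return()
    recurse(i + 1, used_w, count)
    for (j in seq_along(icv_women)) {
      if (!used_w[j] && abs(icv_men[i] - icv_women[j]) < tol) {
        used_w[j] <- TRUE
        recurse(i + 1, used_w, count + 1L)
        used_w[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, length(icv_women)), 0L)
  best
}

# Brute-force BH step-up rejection set.
brute_force_bh <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= alpha * i / m) k <- i
  reject <- rep(FALSE, m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  reject
}

# Random symmetric positive semi-definite 3x3 tensor.
random_psd_tensor <- function() {
  A <- matrix(rnorm(9), 3)
  D <- crossprod(A) * 1e-4
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

# Two well-separated straight-bundle groups for clustering checks.
two_group_streamlines <- function(n_per = 10, gap = 100, jitter = 0.5,
                                  seed = 1) {
  set.seed(seed)
  base <- cbind(seq(0, 24), 0, 0)
  out <- list()
  for (g in 1:2) for (i in seq_len(n_per)) {
    off <- c(0, (g - 1) * gap, 0) + rnorm(3, 0, jitter)
    out[[length(out) + 1]] <- sweep(base, 2, off, "+")
  }
  out
}

# Dense brute-force polyline sampler (independent of the package's
# supersampler): fixed tiny steps along each segment, endpoints included.
supersample_oracle <- function(points, step = 0.01) {
  out <- points[1, , drop = FALSE]
  for (s in seq_len(nrow(points) - 1)) {
    a <- points[s, ]; b <- points[s + 1, ]
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, by = min(1, step / max(len, 1e-12)))
    ts <- unique(c(ts, 1))
    out <- rbind(out, outer(1 - ts, a) + outer(ts, b))
  }
  out
}
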