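test_that("partition is a disjoint cover with the expected sizes", {
  p <- partition_pool(25, subset_size = 10, seed = 3)
  expect_equal(sort(vapply(p, length, 0L), decreasing = TRUE), c(10, 10, 5))
  expect_equal(sort(unlist(p)), 1:25)
  expect_identical(partition_pool(25, 10, seed = 3),
                   partition_pool(25, 10, seed = 3))
  expect_error(partition_pool(0, 10), "non-empty")
  expect_error(partition_pool(10, 0), ">= 1")
})

test_that("label matching recovers a known permutation (Hungarian oracle)", {
  set.seed(5)
  reps <- replicate(5, resample_streamline(
    cbind(cumsum(runif(6)) * 30, rnorm(6, 0, 10), rnorm(6, 0, 10))),
    simplify = FALSE)
  expect_equal(match_labels(reps, reps), 1:5)
  perm <- c(3, 1, 4, 5, 2)
  expect_equal(match_labels(reps, reps[perm]), perm)
  # brute-force assignment oracle over all permutations
  cost <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    cost[i, j] <- streamline_distance(reps[[perm[i]]], reps[[j]])
  }
  all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf; best_p <- NULL
  for (p in all_perms(1:5)) {
    tot <- sum(cost[cbind(1:5, p)])
    if (tot < best - 1e-12) { best <- tot; best_p <- p }
  }
  a <- solve_assignment(cost)
  expect_equal(sum(cost[cbind(1:5, a)]), best, tolerance = 1e-10)
  expect_error(match_labels(reps, reps[1:4]), "same number")
})

test_that("fully tied assignment costs resolve to the identity mapping", {
  cost <- matrix(1, 4, 4)
  expect_equal(solve_assignment(cost), 1:4)
})

test_that("consensus takes modal labels with lowest-label tie-breaks", {
  A <- rbind(c(1, 1, 2),     # modal 1, stability 2/3
             c(2, 2, 2),     # modal 2, stability 1
             c(1, 2, 3))     # full tie -> lowest label 1, stability 1/3
  cons <- consensus_labels(A)
  expect_equal(cons$labels, c(1, 2, 1))
  expect_equal(cons$stability, c(2 / 3, 1, 1 / 3))
  same <- matrix(5, 4, 10)
  cons2 <- consensus_labels(same)
  expect_equal(cons2$stability, rep(1, 4))
  expect_error(consensus_labels(matrix(integer(0), 2, 0)), "at least one")
})

test_that("consensus recovers ground truth under 10% label noise", {
  # binomial tail: P(majority wrong | flip rate .1, r=100) < 1e-16 per item,
  # so >99% recovery is essentially certain
  set.seed(9)
  truth <- sample(1:8, 500, replace = TRUE)
  r <- 100
  A <- matrix(truth, 500, r)
  flips <- matrix(runif(500 * r) < 0.1, 500, r)
  A[flips] <- sample(1:8, sum(flips), replace = TRUE)
  cons <- consensus_labels(A)
  expect_gt(mean(cons$labels == truth), 0.99)
})

test_that("stability is invariant to a common relabeling of repetitions", {
  set.seed(11)
  A <- matrix(sample(1:4, 60, replace = TRUE), 20, 3)
  perm <- c(3, 4, 2, 1)
  B <- matrix(perm[A], 20, 3)
  expect_equal(consensus_labels(A)$stability, consensus_labels(B)$stability)
})

test_that("tract extraction filters by label and stability", {
  cons <- structure(list(labels = c(1L, 1L, 2L, 1L),
                         stability = c(0.4, 0.6, 0.9, 0.9),
                         n_repetitions = 10L),
                    class = "consensus_segmentation")
  expect_equal(extract_tract(cons, 1, stability_min = 0.5), c(2L, 4L))
  expect_equal(extract_tract(cons, c(1, 2), stability_min = 0), 1:4)
  expect_warning(out <- extract_tract(cons, 5), "empty")
  expect_length(out, 0)
})

test_that("small phantom is recovered and subject order does not matter", {
  ph <- build_phantom(n_subjects = 2, n_streamlines = 25, radius = 1.5,
                      seed = 21)
  seg <- cluster_bundles(ph$streamlines, k = 8, subset_size = 150,
                         repetitions = 3, seed = 5)
  expect_gte(adjusted_rand(seg$labels, as.integer(ph$truth)), 0.95)
  # permuting pooled streamline order leaves the partition equivalent
  set.seed(33)
  perm <- sample(seq_along(ph$streamlines))
  seg2 <- cluster_bundles(ph$streamlines[perm], k = 8, subset_size = 150,
                          repetitions = 3, seed = 5)
  expect_gte(adjusted_rand(seg2$labels, as.integer(ph$truth)[perm]), 0.95)
})
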