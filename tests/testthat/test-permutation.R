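small_design <- function(n = 30, seed = 1) {
  set.seed(seed)
  tab <- data.frame(
    subject_id = paste0("S", 1:n),
    sex = rep(c("M", "F"), length.out = n),
    age = runif(n, 50, 66),
    icv_ml = rnorm(n, 1550, 120))
  build_design(tab)
}

test_that("a strong effect reaches the corrected-p floor", {
  set.seed(61)
  n <- 40
  des <- small_design(n, seed = 2)
  units <- 50
  Y <- matrix(rnorm(units * n, 0, 1), units, n)
  # unit 7 carries an effect 10x the noise SD per unit of centered ICV SD
  icv_c <- des$X[, "icv_ml"]
  Y[7, ] <- Y[7, ] + 10 * icv_c / sd(icv_c)
  res <- permutation_inference(Y, des, "icv_ml", n_perm = 199,
                               method = "maxstat", seed = 3)
  expect_equal(res$p_corrected[7], 1 / 200)
  expect_gt(min(res$p_corrected[-7]), 0.2)
})

test_that("corrected p dominates uncorrected p and respects its floor", {
  set.seed(63)
  des <- small_design(24, seed = 4)
  Y <- matrix(rnorm(40 * 24), 40, 24)
  res <- permutation_inference(Y, des, "age", n_perm = 99, seed = 5)
  expect_true(all(res$p_corrected >= res$p_uncorrected - 1e-12))
  expect_true(all(res$p_corrected >= 1 / 100))
  expect_true(all(res$p_corrected <= 1))
  # n_perm = 1: corrected p can only be 1/2 or 1
  res1 <- permutation_inference(Y, des, "age", n_perm = 1, seed = 6)
  expect_true(all(res1$p_corrected %in% c(0.5, 1)))
})

test_that("observed statistics equal the per-unit GLM t statistics", {
  set.seed(65)
  des <- small_design(26, seed = 7)
  Y <- matrix(rnorm(5 * 26), 5, 26)
  res <- permutation_inference(Y, des, "icv_ml", n_perm = 9, seed = 8)
  for (u in 1:5) {
    fit <- fit_glm(Y[u, ], des)
    expect_equal(res$statistic[u],
                 fit$coefficients$t[fit$coefficients$term == "icv_ml"],
                 tolerance = 1e-9)
  }
  expect_error(permutation_inference(Y, des, "nope", n_perm = 9), "not in")
})

test_that("permutation p values are invariant to covariate centering", {
  set.seed(67)
  n <- 24
  tab <- data.frame(subject_id = paste0("S", 1:n),
                    sex = rep(c("M", "F"), length.out = n),
                    age = runif(n, 50, 66),
                    icv_ml = rnorm(n, 1550, 120))
  Y <- matrix(rnorm(20 * n), 20, n)
  r_c <- permutation_inference(Y, build_design(tab, center = TRUE),
                               "icv_ml", n_perm = 99, seed = 9)
  r_u <- permutation_inference(Y, build_design(tab, center = FALSE),
                               "icv_ml", n_perm = 99, seed = 9)
  expect_equal(r_c$statistic, r_u$statistic, tolerance = 1e-8)
  expect_equal(r_c$p_corrected, r_u$p_corrected)
})

test_that("family-wise error is near nominal under the null (quick check)", {
  # small-scale calibration; the full-scale one runs in the acceptance suite
  set.seed(69)
  des <- small_design(30, seed = 10)
  rejections <- 0
  reps <- 60
  for (r in 1:reps) {
    Y <- matrix(rnorm(50 * 30), 50, 30)
    res <- permutation_inference(Y, des, "icv_ml", n_perm = 199,
                                 seed = 1000 + r)
    if (min(res$p_corrected) <= 0.05) rejections <- rejections + 1
  }
  rate <- rejections / reps
  expect_gte(rate, 0.0)
  expect_lte(rate, 0.15)
})

test_that("tfce-corrected inference runs and flags a coherent cluster", {
  set.seed(71)
  n <- 30
  des <- small_design(n, seed = 11)
  units <- 30
  edges <- cbind(1:(units - 1), 2:units)   # a line graph
  Y <- matrix(rnorm(units * n), units, n)
  icv_c <- des$X[, "icv_ml"]
  for (u in 10:14) Y[u, ] <- Y[u, ] + 6 * icv_c / sd(icv_c)
  res <- permutation_inference(Y, des, "icv_ml", n_perm = 99,
                               method = "tfce", edges = edges, seed = 12)
  expect_lt(max(res$p_corrected[10:14]), 0.05)
})
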