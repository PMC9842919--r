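make_tensor_array <- function(d6_list) {
  array(do.call(rbind, d6_list), c(length(d6_list), 1, 1, 6))
}

test_that("b=0 signal equals s0 and isotropic tensors give isotropic signal", {
  sch <- default_scheme()
  D_iso <- c(7e-4, 7e-4, 7e-4, 0, 0, 0)
  dwi <- simulate_dwi(make_tensor_array(list(D_iso)), sch, s0 = 500)
  sig <- dwi[1, 1, 1, ]
  expect_equal(unname(sig[sch$bvals == 0]), rep(500, 5))
  dw <- sig[sch$bvals > 0]
  expect_equal(max(dw) - min(dw), 0, tolerance = 1e-12)
  expect_equal(unname(dw[1]), 500 * exp(-1000 * 7e-4), tolerance = 1e-12)
})

test_that("non-PSD tensors are rejected; Rician noise is seeded", {
  sch <- default_scheme()
  bad <- c(-1e-3, 1e-3, 1e-3, 0, 0, 0)
  expect_error(simulate_dwi(make_tensor_array(list(bad)), sch),
               "positive semi-definite")
  ok <- make_tensor_array(list(c(1e-3, 1e-3, 1e-3, 0, 0, 0)))
  a <- simulate_dwi(ok, sch, snr = 20, seed = 5)
  b <- simulate_dwi(ok, sch, snr = 20, seed = 5)
  c <- simulate_dwi(ok, sch, snr = 20, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("noiseless tensor round-trip recovers eigenvalues to 1e-9", {
  sch <- default_scheme()
  D <- c(1.7e-3, 0.2e-3, 0.2e-3, 0, 0, 0)
  dwi <- simulate_dwi(make_tensor_array(list(D)), sch)
  fit <- fit_tensor(dwi, sch)
  ev <- fit$eigenvalues[1, 1, 1, ]
  expect_equal(ev, c(1.7e-3, 0.2e-3, 0.2e-3), tolerance = 1e-9)
  # rotated anisotropic tensor round-trips too
  set.seed(8)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  Dm <- R %*% diag(c(1.7, 0.5, 0.2) * 1e-3) %*% t(R)
  d6 <- c(Dm[1, 1], Dm[2, 2], Dm[3, 3], Dm[1, 2], Dm[1, 3], Dm[2, 3])
  fit2 <- fit_tensor(simulate_dwi(make_tensor_array(list(d6)), sch), sch)
  expect_equal(fit2$eigenvalues[1, 1, 1, ], c(1.7, 0.5, 0.2) * 1e-3,
               tolerance = 1e-9)
})

test_that("tensor fit validates the scheme and flags bad voxels", {
  sch <- default_scheme()
  expect_error(dwi_scheme(c(-1, 0), matrix(0, 2, 3)), "non-negative")
  D <- make_tensor_array(list(c(1e-3, 1e-3, 1e-3, 0, 0, 0)))
  dwi <- simulate_dwi(D, sch)
  dwi_bad <- dwi
  dwi_bad[1, 1, 1, 3] <- 0
  fit <- fit_tensor(dwi_bad, sch)
  expect_false(fit$valid[1, 1, 1])
  expect_true(all(is.na(fit$eigenvalues[1, 1, 1, ])))
  expect_error(fit_tensor(dwi[, , , 1:6, drop = FALSE],
                          dwi_scheme(sch$bvals[1:6], sch$bvecs[1:6, ])),
               ">= 6")
})

test_that("duplicated gradient rows give the same fit as the unique scheme", {
  sch <- default_scheme(n_dirs = 12)
  idx <- c(seq_along(sch$bvals), 6, 7)   # duplicate two rows
  sch_dup <- dwi_scheme(sch$bvals[idx], sch$bvecs[idx, ])
  D <- make_tensor_array(list(c(1.4e-3, 0.6e-3, 0.3e-3, 1e-4, 0, -5e-5)))
  dwi <- simulate_dwi(D, sch)
  dwi_dup <- simulate_dwi(D, sch_dup)
  f1 <- fit_tensor(dwi, sch)
  f2 <- fit_tensor(dwi_dup, sch_dup)
  # noiseless: duplicated consistent equations leave the LS solution unchanged
  expect_equal(f2$eigenvalues, f1$eigenvalues, tolerance = 1e-10)
})

test_that("scalar indices match closed forms and stay in range", {
  ev <- array(c(1.7e-3, 0.2e-3, 0.2e-3), c(1, 3))
  idx <- compute_indices(ev)
  expect_equal(idx$fa[1], 0.8703883, tolerance = 1e-6)
  expect_equal(idx$md[1], 0.7e-3)
  expect_equal(idx$ad[1], 1.7e-3)
  expect_equal(idx$rd[1], 0.2e-3)
  # isotropy, degenerate and limit cases
  expect_equal(compute_indices(array(c(5e-4, 5e-4, 5e-4), c(1, 3)))$fa[1], 0)
  expect_equal(compute_indices(array(c(0, 0, 0), c(1, 3)))$fa[1], 0)
  expect_equal(compute_indices(array(c(1, 0, 0), c(1, 3)))$fa[1], 1)
})

test_that("FA is scale-invariant, in [0,1], and MD = (AD + 2 RD)/3", {
  set.seed(21)
  for (i in 1:50) {
    d6 <- random_psd_tensor()
    ev <- sort(eigen(matrix(c(d6[1], d6[4], d6[5], d6[4], d6[2], d6[6],
                              d6[5], d6[6], d6[3]), 3),
                     symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    idx <- compute_indices(array(ev, c(1, 3)))
    idx_scaled <- compute_indices(array(3.7 * ev, c(1, 3)))
    expect_gte(idx$fa[1], 0)
    expect_lte(idx$fa[1], 1)
    expect_equal(idx$fa[1], idx_scaled$fa[1], tolerance = 1e-12)
    expect_equal(idx$md[1], (idx$ad[1] + 2 * idx$rd[1]) / 3,
                 tolerance = 1e-15)
  }
})
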