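test_that("design building centers covariates and forms interactions", {
  tab <- generate_cohort(cohort_spec(n_men = 15, n_women = 15, seed = 2))
  des <- build_design(tab, interactions = c("icv_ml:sex", "icv_ml:age",
                                            "sex:icv_ml:age"))
  expect_equal(mean(des$X[, "icv_ml"]), 0, tolerance = 1e-10)
  expect_equal(mean(des$X[, "age"]), 0, tolerance = 1e-10)
  expect_equal(des$X[, "icv_ml:sex"], des$X[, "icv_ml"] * des$X[, "sexF"],
               ignore_attr = TRUE)
  expect_equal(des$X[, "sex:icv_ml:age"],
               des$X[, "sexF"] * des$X[, "icv_ml"] * des$X[, "age"],
               ignore_attr = TRUE)
  expect_error(build_design(tab, covariates = "nope"), "no column")
})

test_that("noiseless responses are interpolated exactly", {
  tab <- generate_cohort(cohort_spec(n_men = 20, n_women = 20, seed = 3))
  des <- build_design(tab)
  y <- drop(des$X %*% c(0.35, 5e-5, -3e-4, 0.004))
  fit <- fit_glm(y, des)
  expect_equal(fit$coefficients$beta, c(0.35, 5e-5, -3e-4, 0.004),
               tolerance = 1e-10)
  expect_lt(fit$rss, 1e-20)
})

test_that("fit matches stats::lm inference and eta squared identity", {
  set.seed(31)
  tab <- generate_cohort(cohort_spec(n_men = 60, n_women = 60, seed = 7))
  y <- tab$cc_fa
  des <- build_design(tab)
  fit <- fit_glm(y, des)
  ref <- lm(y ~ I(icv_ml - mean(icv_ml)) + I(age - mean(age)) +
              I(sex == "F"), data = tab)
  sm <- summary(ref)$coefficients
  expect_equal(fit$coefficients$beta, unname(sm[, 1]), tolerance = 1e-10)
  expect_equal(fit$coefficients$se, unname(sm[, 2]), tolerance = 1e-10)
  expect_equal(fit$coefficients$p, unname(sm[, 4]), tolerance = 1e-10)
  # partial eta^2 for single-df terms: t^2/(t^2 + df)
  tv <- fit$coefficients$t
  expect_equal(fit$coefficients$eta_sq_partial,
               tv^2 / (tv^2 + fit$df_residual))
  expect_true(all(fit$coefficients$eta_sq_partial >= 0 &
                  fit$coefficients$eta_sq_partial <= 1))
  # fitted + residual SS = total SS (with intercept)
  expect_equal(sum((fit$fitted - mean(y))^2) + fit$rss, fit$tss,
               tolerance = 1e-10)
})

test_that("slopes and inference are invariant to covariate centering", {
  tab <- generate_cohort(cohort_spec(n_men = 40, n_women = 40, seed = 9))
  y <- tab$cg_fa
  f_c <- fit_glm(y, build_design(tab, center = TRUE))
  f_u <- fit_glm(y, build_design(tab, center = FALSE))
  keep <- f_c$coefficients$term != "(Intercept)"
  expect_equal(f_c$coefficients$beta[keep], f_u$coefficients$beta[keep],
               tolerance = 1e-10)
  expect_equal(f_c$coefficients$t[keep], f_u$coefficients$t[keep],
               tolerance = 1e-8)
  expect_equal(f_c$coefficients$eta_sq_partial[keep],
               f_u$coefficients$eta_sq_partial[keep], tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected with the offending column", {
  tab <- generate_cohort(cohort_spec(n_men = 10, n_women = 10, seed = 4))
  X <- build_design(tab)$X
  X <- cbind(X, dup = X[, "icv_ml"])
  expect_error(fit_glm(tab$cc_fa, X), "collinear")
})

test_that("null-effect partial eta squared has mean ~ 1/(n - p)", {
  set.seed(41)
  n <- 60; reps <- 300
  tab <- generate_cohort(cohort_spec(n_men = 30, n_women = 30, seed = 6))
  des <- build_design(tab)
  etas <- replicate(reps, {
    y <- rnorm(n)                        # no true effect of anything
    fit <- fit_glm(y, des)
    fit$coefficients$eta_sq_partial[fit$coefficients$term == "icv_ml"]
  })
  df <- n - 4
  # E[eta^2] = E[t^2/(t^2+df)]; t ~ t_df under the null, mean ~ 1/(df+ ~0)
  expect_lt(abs(mean(etas) - 1 / df), 3 * sd(etas) / sqrt(reps) + 0.005)
})

test_that("interaction screening drops null terms and keeps strong ones", {
  set.seed(51)
  drop_count <- 0
  for (i in 1:10) {
    spec <- cohort_spec(n_men = 400, n_women = 400, seed = 100 + i)
    tab <- generate_cohort(spec)      # generator has no interactions
    scr <- interaction_screen(tab$cc_fa, tab)
    if (length(scr$dropped) == 3) drop_count <- drop_count + 1
  }
  expect_gte(drop_count, 9)
  # inject a strong ICV x sex interaction (>> its SE)
  spec <- cohort_spec(n_men = 400, n_women = 400, seed = 77)
  tab <- generate_cohort(spec)
  female <- as.numeric(tab$sex == "F")
  y <- tab$cc_fa + 4e-4 * (tab$icv_ml - mean(tab$icv_ml)) * female
  scr <- interaction_screen(y, tab)
  expect_true("icv_ml:sex" %in% scr$retained)
  # alpha = 0 drops everything
  scr0 <- interaction_screen(y, tab, alpha = 0)
  expect_length(scr0$retained, 0)
})
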