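#' Build a mean-centered design matrix
#'
#' Columns: intercept, continuous covariates (mean-centered), a 0/1 female
#' indicator, and optional pairwise/three-way interaction products of the
#' centered columns. Centering makes main effects interpretable at the
#' cohort mean and leaves all non-intercept estimates unchanged.
#'
#' @param table Subject data frame with `sex` (`"M"`/`"F"`) and the named
#'   covariate columns.
#' @param covariates Character vector of continuous covariate column names
#'   (default `c("icv_ml", "age")`).
#' @param sex Logical: include the female indicator (default TRUE).
#' @param interactions Character vector of interaction terms like
#'   `"icv_ml:sex"` or `"icv_ml:sex:age"`, formed as products of the
#'   centered columns; default none.
#' @param center Center continuous covariates (default TRUE).
#' @return List of class `design_matrix`: `X` (numeric matrix with named
#'   columns, first column `"(Intercept)"`), `centering` (named means
#'   subtracted), `terms` (non-intercept column names).
#' @export
build_design <- function(table, covariates = c("icv_ml", "age"),
                         sex = TRUE, interactions = character(0),
                         center = TRUE) {
  n <- nrow(table)
  cols <- list(`(Intercept)` = rep(1, n))
  centering <- numeric(0)
  base <- list()
  for (cv in covariates) {
    x <- table[[cv]]
    if (is.null(x)) stop("no column ", cv, call. = FALSE)
    mu <- if (center) mean(x) else 0
    centering[cv] <- mu
    base[[cv]] <- x - mu
    cols[[cv]] <- base[[cv]]
  }
  if (sex) {
    base[["sex"]] <- as.numeric(table$sex == "F")
    cols[["sexF"]] <- base[["sex"]]
  }
  for (it in interactions) {
    parts <- strsplit(it, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% names(base))) {
      stop("unknown interaction component in ", it, call. = FALSE)
    }
    cols[[paste(parts, collapse = ":")]] <-
      Reduce(`*`, base[parts])
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(X = X, centering = centering,
                 terms = setdiff(colnames(X), "(Intercept)")),
            class = "design_matrix")
}

#' Ordinary least squares fit with per-term inference and effect sizes
#'
#' Fits `y = X b + e` by QR least squares and reports per-term
#' unstandardized coefficients, standard errors, t statistics, two-sided p
#' values and partial eta squared. For single-df terms the Type-III partial
#' eta squared reduces to `t^2 / (t^2 + df_residual)`.
#'
#' @param y Numeric response vector.
#' @param design A `design_matrix` from [build_design()], or a plain numeric
#'   matrix (first column treated as intercept).
#' @return List of class `regression_fit`: `coefficients` (data frame with
#'   `term`, `beta`, `se`, `t`, `p`, `eta_sq_partial`), `sigma`,
#'   `df_residual`, `rss`, `tss`, `fitted`, `residuals`.
#' @export
fit_glm <- function(y, design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)", call. = FALSE)
  if (n <= p) stop("need n > p", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- rss / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)
  eta <- tval^2 / (tval^2 + df)
  coef_tab <- data.frame(term = colnames(X), beta = unname(beta),
                         se = unname(se), t = unname(tval), p = unname(pval),
                         eta_sq_partial = unname(eta),
                         stringsAsFactors = FALSE)
  structure(list(coefficients = coef_tab, sigma = sqrt(sigma2),
                 df_residual = df, rss = rss,
                 tss = sum((y - mean(y))^2),
                 fitted = fitted, residuals = res),
            class = "regression_fit")
}

#' Screen and drop non-significant interaction terms
#'
#' Fits the full model including the supplied interaction terms, corrects
#' the interaction p values with Benjamini-Hochberg as one family, drops
#' every interaction whose corrected p is at or above `alpha`, and returns
#' the reduced design. Mirrors the practice of adding ICV x sex, ICV x age
#' and sex x ICV x age terms, removing them when no interaction is found.
#'
#' @param y Response vector.
#' @param table Subject table (passed to [build_design()]).
#' @param covariates,interactions As in [build_design()].
#' @param alpha Significance level (default 0.05).
#' @return List: `design` (reduced `design_matrix`), `dropped`, `retained`
#'   (character vectors of interaction terms), `full_fit`.
#' @export
interaction_screen <- function(y, table, covariates = c("icv_ml", "age"),
                               interactions = c("icv_ml:sex", "icv_ml:age",
                                                "sex:icv_ml:age"),
                               alpha = 0.05) {
  full <- build_design(table, covariates, sex = TRUE,
                       interactions = interactions)
  fit <- fit_glm(y, full)
  ct <- fit$coefficients
  canon <- function(s) vapply(strsplit(s, ":", fixed = TRUE),
                              function(p) paste(sort(p), collapse = ":"), "")
  is_int <- grepl(":", ct$term, fixed = TRUE)
  pvals <- ct$p[is_int]
  padj <- p.adjust(pvals, method = "BH")
  keep_int <- ct$term[is_int][padj < alpha]
  retained <- interactions[canon(interactions) %in% canon(keep_int)]
  dropped <- setdiff(interactions, retained)
  reduced <- build_design(table, covariates, sex = TRUE,
                          interactions = retained)
  list(design = reduced, dropped = dropped, retained = retained,
       full_fit = fit)
}
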