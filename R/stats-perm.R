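#' Permutation inference for one GLM term across many units
#'
#' Freedman-Lane permutation test of a single design term, run jointly over
#' many response units (voxels or tracts) with family-wise error control.
#' The reduced model (all columns except the tested term) is fitted per
#' unit; its residuals are permuted, added back to the reduced fit, and the
#' full-model t statistic for the term is recomputed. Family-wise corrected
#' p values come from the permutation distribution of the maximum |t| over
#' units (`method = "maxstat"`) or of the maximum TFCE-enhanced |t|
#' (`method = "tfce"`, which requires a neighborhood `edges` graph). The
#' observed statistic is included in the null sample, so
#' `p = (1 + #(perm >= obs)) / (n_perm + 1)` with floor `1/(n_perm+1)`.
#'
#' @param responses Numeric matrix, units x subjects.
#' @param design A `design_matrix` or plain design matrix (subjects x terms).
#' @param term Name (or index) of the tested column.
#' @param n_perm Number of permutations (default 5000).
#' @param method `"maxstat"` or `"tfce"`.
#' @param edges Two-column integer matrix of unit adjacencies (for
#'   `method = "tfce"`); units with no edges are isolated.
#' @param tfce_h,tfce_e TFCE exponents (defaults H = 2, E = 0.5).
#' @param seed Integer seed.
#' @return List of class `permutation_result`: `statistic` (observed t per
#'   unit), `p_corrected`, `p_uncorrected`, `n_permutations`, `method`,
#'   `seed`.
#' @export
permutation_inference <- function(responses, design, term, n_perm = 5000L,
                                  method = c("maxstat", "tfce"),
                                  edges = NULL, tfce_h = 2, tfce_e = 0.5,
                                  seed = 1L) {
  method <- match.arg(method)
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  Y <- as.matrix(responses)
  n <- ncol(Y)
  if (nrow(X) != n) stop("design rows must match subjects", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (is.character(term)) {
    j <- match(term, colnames(X))
    if (is.na(j)) stop("term '", term, "' not in design", call. = FALSE)
  } else {
    j <- as.integer(term)
    if (j < 1 || j > ncol(X)) stop("term index out of range", call. = FALSE)
  }
  p <- ncol(X)
  df <- n - p
  if (df < 1) stop("need n > p", call. = FALSE)

  XtX_inv <- chol2inv(chol(crossprod(X)))
  H <- XtX_inv %*% t(X)                 # p x n: beta = H %*% y
  cvar <- XtX_inv[j, j]
  Q <- qr.Q(qr(X))                      # n x p orthonormal basis

  tstat <- function(Ymat) {
    # Ymat: n x units
    beta_j <- drop(H[j, , drop = FALSE] %*% Ymat)
    rss <- colSums(Ymat^2) - colSums((crossprod(Q, Ymat))^2)
    rss[rss < 0] <- 0
    beta_j / sqrt(pmax(rss / df, .Machine$double.xmin) * cvar)
  }

  enhance <- function(tv) {
    if (method == "maxstat") return(abs(tv))
    pmax(tfce_enhance(pmax(tv, 0), edges, H = tfce_h, E = tfce_e),
         tfce_enhance(pmax(-tv, 0), edges, H = tfce_h, E = tfce_e))
  }

  Yt <- t(Y)                            # n x units
  t_obs <- tstat(Yt)
  s_obs <- enhance(t_obs)

  # reduced model: all columns but j
  Xr <- X[, -j, drop = FALSE]
  Qr <- qr.Q(qr(Xr))
  Fit_r <- Qr %*% crossprod(Qr, Yt)     # reduced-model fitted values
  E_r <- Yt - Fit_r

  set.seed(seed)
  exceed <- rep(0L, length(s_obs))
  max_null <- numeric(n_perm)
  unit_exceed <- rep(0L, length(t_obs))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    Ystar <- Fit_r + E_r[perm, , drop = FALSE]
    tb <- tstat(Ystar)
    sb <- enhance(tb)
    max_null[b] <- max(sb)
    unit_exceed <- unit_exceed + (abs(tb) >= abs(t_obs))
  }
  p_corr <- (1 + vapply(s_obs, function(s) sum(max_null >= s), 0L)) /
    (n_perm + 1)
  p_unc <- (1 + unit_exceed) / (n_perm + 1)
  structure(list(statistic = t_obs, p_corrected = pmin(p_corr, 1),
                 p_uncorrected = pmin(p_unc, 1),
                 n_permutations = as.integer(n_perm),
                 method = method, seed = as.integer(seed)),
            class = "permutation_result")
}

#' Threshold-free cluster enhancement
#'
#' Enhances a non-negative statistic map by integrating, over thresholds
#' `h` from `dh` to the map maximum in steps of `dh`, each unit's
#' supporting-cluster extent raised to `E` times `h^H`:
#' `enhanced(v) = sum_h extent(cluster_h(v))^E * h^H * dh`, with clusters
#' the connected components of the supra-threshold units on the supplied
#' neighborhood graph. Negative contrasts are enhanced separately on the
#' negated map.
#'
#' @param stat Non-negative numeric vector (one value per unit).
#' @param edges Two-column integer matrix of undirected unit adjacencies;
#'   `NULL` means all units are isolated (extent 1).
#' @param H Height exponent (default 2).
#' @param E Extent exponent (default 0.5).
#' @param dh Threshold step; default `max(stat)/100`.
#' @return Numeric vector of enhanced values.
#' @export
tfce_enhance <- function(stat, edges = NULL, H = 2, E = 0.5, dh = NULL) {
  if (any(stat < 0)) {
    stop("stat must be non-negative; enhance negated map separately",
         call. = FALSE)
  }
  n <- length(stat)
  mx <- max(stat)
  if (mx == 0) return(numeric(n))
  if (is.null(dh)) dh <- mx / 100
  if (dh <= 0) stop("dh must be positive", call. = FALSE)
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns", call. = FALSE)
  }
  out <- numeric(n)
  hs <- seq(dh, mx, by = dh)
  for (h in hs) {
    active <- stat >= h
    if (!any(active)) break
    comp <- components_at(active, edges, n)
    ext <- tabulate(comp, nbins = max(comp, na.rm = TRUE))
    idx <- which(active)
    out[idx] <- out[idx] + ext[comp[idx]]^E * h^H * dh
  }
  out
}

# Connected components among active units via union-find on the edge list.
components_at <- function(active, edges, n) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (!is.null(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      if (active[a] && active[b]) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  comp <- rep(NA_integer_, n)
  act <- which(active)
  roots <- vapply(act, find, 0L)
  comp[act] <- match(roots, unique(roots))
  comp
}

#' Benjamini-Hochberg correction within families
#'
#' Step-up false-discovery-rate control applied independently within each
#' family of tests (e.g. ICV effects, sex effects, age effects).
#'
#' @param p Numeric p values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @param families Optional vector of family identifiers, same length as
#'   `p`; default puts everything in one family.
#' @return Data frame with `p`, `family`, `p_adjusted`, `reject`.
#' @export
bh_correct <- function(p, alpha = 0.05, families = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p values must be in [0, 1]", call. = FALSE)
  }
  if (is.null(families)) families <- rep(1L, length(p))
  if (length(families) != length(p)) {
    stop("families must match p in length", call. = FALSE)
  }
  padj <- numeric(length(p))
  for (f in unique(families)) {
    idx <- families == f
    padj[idx] <- p.adjust(p[idx], method = "BH")
  }
  data.frame(p = p, family = families, p_adjusted = padj,
             reject = padj <= alpha)
}
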