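#' Diffusion gradient scheme
#'
#' A b-value vector (s/mm^2) and unit gradient directions. The default
#' scheme has 40 unique non-collinear directions at b = 1000 s/mm^2 plus 5
#' b = 0 volumes.
#'
#' @param bvals Numeric vector of b-values, >= 0.
#' @param bvecs Matrix with one unit row vector per volume (rows for b = 0
#'   volumes may be zero).
#' @return Object of class `dwi_scheme`.
#' @export
dwi_scheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (length(bvals) != nrow(bvecs) || ncol(bvecs) != 3) {
    stop("bvecs must be length(bvals) x 3", call. = FALSE)
  }
  if (any(bvals < 0)) stop("bvals must be non-negative", call. = FALSE)
  nz <- bvals > 0
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[nz] - 1) > 1e-6)) {
    stop("gradient directions for b > 0 must be unit vectors", call. = FALSE)
  }
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
            class = "dwi_scheme")
}

#' @rdname dwi_scheme
#' @param n_dirs Number of diffusion directions.
#' @param b Shell b-value in s/mm^2.
#' @param n_b0 Number of b = 0 volumes (prepended).
#' @export
default_scheme <- function(n_dirs = 40L, b = 1000, n_b0 = 5L) {
  # deterministic quasi-uniform directions on the half sphere (Fibonacci)
  i <- seq_len(n_dirs) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n_dirs            # upper half sphere suffices for DTI
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  dwi_scheme(c(rep(0, n_b0), rep(b, n_dirs)),
             rbind(matrix(0, n_b0, 3), dirs))
}

tensor6_to_mat <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

mat_to_tensor6 <- function(D) {
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

#' Simulate a diffusion-weighted volume set
#'
#' Mono-exponential tensor signal `S = s0 * exp(-b * g' D g)` per voxel and
#' gradient, with optional Rician noise: the magnitude of the complex signal
#' after adding independent Gaussian noise of SD `s0/snr` to both channels.
#' `snr = Inf` gives the deterministic noiseless signal.
#'
#' @param tensors Numeric array `c(dim, 6)`: per-voxel tensor in
#'   `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)` order, mm^2/s; tensors must be
#'   positive semi-definite. `dim` may be any spatial shape, e.g. `c(nx,ny,nz)`.
#' @param scheme A [dwi_scheme()].
#' @param s0 Baseline (b = 0) signal.
#' @param snr Signal-to-noise ratio at b = 0; `Inf` for noiseless.
#' @param seed Integer seed (used only when `snr < Inf`).
#' @return Numeric array `c(dim, n_volumes)` of signals, with the scheme
#'   attached as attribute `"scheme"`.
#' @export
simulate_dwi <- function(tensors, scheme, s0 = 1000, snr = Inf, seed = 1L) {
  stopifnot(inherits(scheme, "dwi_scheme"))
  dims <- dim(tensors)
  if (is.null(dims) || dims[length(dims)] != 6) {
    stop("tensors must be an array with last dimension 6", call. = FALSE)
  }
  sp <- dims[-length(dims)]
  nvox <- prod(sp)
  D6 <- matrix(tensors, nvox, 6)
  # PSD check per voxel via eigenvalues
  for (v in seq_len(nvox)) {
    ev <- eigen(tensor6_to_mat(D6[v, ]), symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-12 * max(abs(ev), 1e-30)) {
      stop("tensor at voxel ", v, " is not positive semi-definite",
           call. = FALSE)
    }
  }
  g <- scheme$bvecs
  b <- scheme$bvals
  # b * g' D g for all volumes x voxels: design on tensor components
  q <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  att <- tcrossprod(D6, q * b)          # nvox x nvol
  sig <- s0 * exp(-att)
  if (is.finite(snr)) {
    if (snr <= 0) stop("snr must be positive or Inf", call. = FALSE)
    set.seed(seed)
    sigma <- s0 / snr
    n1 <- matrix(rnorm(length(sig), 0, sigma), nrow(sig))
    n2 <- matrix(rnorm(length(sig), 0, sigma), nrow(sig))
    sig <- sqrt((sig + n1)^2 + n2^2)
  }
  out <- array(sig, c(sp, length(b)))
  attr(out, "scheme") <- scheme
  out
}
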