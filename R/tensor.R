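#' Fit the diffusion tensor by log-linear least squares
#'
#' Per voxel, solves `log S = log s0 - b g' D g` for the six unique tensor
#' components by ordinary least squares on the log signal. Requires at least
#' six non-zero-b directions and one b = 0 volume (7 usable volumes).
#' Voxels with any non-positive signal are flagged invalid (all-NA tensor).
#'
#' @param dwi Array `c(dim, n_volumes)` of signals (e.g. from
#'   [simulate_dwi()]).
#' @param scheme A [dwi_scheme()] matching the last dimension of `dwi`.
#' @return List of class `tensor_fit`: `eigenvalues` (array `c(dim, 3)`,
#'   sorted descending), `eigenvectors` (array `c(dim, 3, 3)`, columns are
#'   unit eigenvectors matching the sorted eigenvalues), `tensors`
#'   (array `c(dim, 6)`), `s0` (array `dim`), `valid` (logical array `dim`).
#' @export
fit_tensor <- function(dwi, scheme) {
  stopifnot(inherits(scheme, "dwi_scheme"))
  dims <- dim(dwi)
  nvol <- dims[length(dims)]
  sp <- dims[-length(dims)]
  if (nvol != length(scheme$bvals)) {
    stop("dwi volume count does not match scheme", call. = FALSE)
  }
  if (sum(scheme$bvals > 0) < 6 || sum(scheme$bvals == 0) < 1 || nvol < 7) {
    stop("need >= 6 diffusion-weighted volumes and >= 1 b=0 volume",
         call. = FALSE)
  }
  g <- scheme$bvecs; b <- scheme$bvals
  X <- cbind(1, -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                           2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                           2 * g[, 2] * g[, 3]))
  nvox <- prod(sp)
  S <- matrix(dwi, nvox, nvol)
  valid <- apply(S > 0, 1, all)
  coefs <- matrix(NA_real_, nvox, 7)
  if (any(valid)) {
    Y <- t(log(S[valid, , drop = FALSE]))
    coefs[valid, ] <- t(qr.coef(qr(X), Y))
  }
  ev <- matrix(NA_real_, nvox, 3)
  evec <- array(NA_real_, c(nvox, 3, 3))
  for (v in which(valid)) {
    e <- eigen(tensor6_to_mat(coefs[v, 2:7]), symmetric = TRUE)
    ev[v, ] <- e$values          # eigen() returns decreasing order
    evec[v, , ] <- e$vectors
  }
  structure(list(
    eigenvalues = array(ev, c(sp, 3)),
    eigenvectors = array(evec, c(sp, 3, 3)),
    tensors = array(coefs[, 2:7], c(sp, 6)),
    s0 = array(exp(coefs[, 1]), sp),
    valid = array(valid, sp)
  ), class = "tensor_fit")
}

#' Scalar diffusion indices from a tensor fit
#'
#' Computes the four standard DTI indices from the sorted eigenvalues
#' `l1 >= l2 >= l3`:
#' * FA = sqrt(1/2) * sqrt(((l1-l2)^2 + (l2-l3)^2 + (l1-l3)^2) /
#'   (l1^2 + l2^2 + l3^2)), defined as 0 for the all-zero tensor;
#' * MD = (l1 + l2 + l3) / 3;
#' * AD = l1;
#' * RD = (l2 + l3) / 2.
#'
#' @param fit A `tensor_fit` from [fit_tensor()], or an array `c(dim, 3)` of
#'   sorted eigenvalues.
#' @return Named list of arrays `fa`, `md`, `ad`, `rd` on the spatial grid.
#' @export
compute_indices <- function(fit) {
  ev <- if (inherits(fit, "tensor_fit")) fit$eigenvalues else fit
  dims <- dim(ev)
  if (is.null(dims)) { ev <- matrix(ev, 1); dims <- c(1L, 3L) }
  if (dims[length(dims)] != 3) {
    stop("eigenvalue array must have last dimension 3", call. = FALSE)
  }
  sp <- dims[-length(dims)]
  L <- matrix(ev, prod(sp), 3)
  l1 <- L[, 1]; l2 <- L[, 2]; l3 <- L[, 3]
  den <- l1^2 + l2^2 + l3^2
  num <- (l1 - l2)^2 + (l2 - l3)^2 + (l1 - l3)^2
  fa <- ifelse(den > 0, sqrt(0.5 * num / den), 0)
  fa[den == 0 & !is.na(den)] <- 0      # degenerate all-zero tensor
  list(fa = array(fa, sp),
       md = array((l1 + l2 + l3) / 3, sp),
       ad = array(l1, sp),
       rd = array((l2 + l3) / 2, sp))
}
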