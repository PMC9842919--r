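#' Scan-to-scan root-mean-squared head motion
#'
#' For each consecutive pair of volume-to-reference affine transforms
#' `T1, T2`, the displacement transform is `M = T2 T1^{-1} - I` with 3x3
#' part `A` and translation `t`, and the RMS displacement over a sphere of
#' radius `R` approximating the head is
#' `rms = sqrt(R^2/5 * trace(A'A) + t't)` (in mm). `rms_mean` averages the
#' per-transition values attributed to diffusion-weighted volumes.
#'
#' @param affines List of 4x4 affine matrices, one per volume, in
#'   acquisition order; at least 2.
#' @param radius Sphere radius in mm (default 80).
#' @param is_dw Optional logical per volume, TRUE for diffusion-weighted
#'   (b > 0) volumes; a transition is included in `rms_mean` when its second
#'   volume is diffusion weighted. Default: all transitions included.
#' @return List of class `motion_trace`: `rms` (length `n-1`), `rms_mean`,
#'   `radius`.
#' @export
motion_rms <- function(affines, radius = 80, is_dw = NULL) {
  if (length(affines) < 2) stop("need at least 2 affines", call. = FALSE)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  n <- length(affines)
  rms <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    T1 <- affines[[i]]; T2 <- affines[[i + 1]]
    if (!all(dim(T1) == c(4, 4)) || !all(dim(T2) == c(4, 4))) {
      stop("affines must be 4x4 matrices", call. = FALSE)
    }
    if (abs(det(T1)) < 1e-12 || abs(det(T2)) < 1e-12) {
      stop("singular affine at volume ", i, call. = FALSE)
    }
    M <- T2 %*% solve(T1) - diag(4)
    A <- M[1:3, 1:3]; t <- M[1:3, 4]
    rms[i] <- sqrt(radius^2 / 5 * sum(A * A) + sum(t * t))
  }
  keep <- if (is.null(is_dw)) rep(TRUE, n - 1) else as.logical(is_dw[-1])
  structure(list(rms = rms, rms_mean = mean(rms[keep]), radius = radius),
            class = "motion_trace")
}
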