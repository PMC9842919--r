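#' Resample a streamline to equally spaced arc-length points
#'
#' Linearly resamples a polyline to `n` points at equal arc-length spacing;
#' the first and last points of the input are preserved exactly.
#'
#' @param points Numeric matrix, one 3D point per row, at least 2 distinct
#'   points with positive total length.
#' @param n Output point count (default 25).
#' @return An `n` x 3 matrix.
#' @export
resample_streamline <- function(points, n = 25L) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points", call. = FALSE)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  total <- sum(seg)
  if (total <= 0) stop("zero-length streamline", call. = FALSE)
  s <- c(0, cumsum(seg))
  target <- seq(0, total, length.out = n)
  out <- cbind(approx(s, points[, 1], xout = target, ties = "ordered")$y,
               approx(s, points[, 2], xout = target, ties = "ordered")$y,
               approx(s, points[, 3], xout = target, ties = "ordered")$y)
  out[1, ] <- points[1, ]
  out[n, ] <- points[nrow(points), ]
  out
}

#' Flip-invariant mean point-to-point distance between two streamlines
#'
#' `d(a, b) = min(mean_i |a_i - b_i|, mean_i |a_i - b_{n+1-i}|)` — the mean
#' Euclidean distance over corresponding points, minimized over the two point
#' orderings of `b` so that orientation flips do not matter.
#'
#' @param a,b Matrices with the same number of rows (points).
#' @return Distance in mm.
#' @export
streamline_distance <- function(a, b) {
  if (nrow(a) != nrow(b)) stop("point counts differ", call. = FALSE)
  d1 <- mean(sqrt(rowSums((a - b)^2)))
  d2 <- mean(sqrt(rowSums((a - b[rev(seq_len(nrow(b))), , drop = FALSE])^2)))
  min(d1, d2)
}

#' Pairwise flip-invariant distance matrix
#'
#' Computes [streamline_distance()] between every pair of resampled
#' streamlines, vectorized over point indices.
#'
#' @param streamlines List of `n_points` x 3 matrices, all with the same
#'   point count.
#' @return Symmetric zero-diagonal matrix (mm).
#' @export
streamline_distance_matrix <- function(streamlines) {
  n <- length(streamlines)
  np <- nrow(streamlines[[1]])
  if (any(vapply(streamlines, nrow, 0L) != np)) {
    stop("all streamlines must have the same point count", call. = FALSE)
  }
  # stack coordinates per point index: list of n x 3 slices
  D1 <- matrix(0, n, n); D2 <- matrix(0, n, n)
  P <- array(0, c(n, np, 3))
  for (s in seq_len(n)) P[s, , ] <- streamlines[[s]]
  for (i in seq_len(np)) {
    Xi <- P[, i, , drop = TRUE]
    Xr <- P[, np + 1 - i, , drop = TRUE]
    if (n == 1) { Xi <- matrix(Xi, 1); Xr <- matrix(Xr, 1) }
    sq <- rowSums(Xi^2)
    G <- tcrossprod(Xi)
    D1 <- D1 + sqrt(pmax(0, outer(sq, sq, "+") - 2 * G))
    sqr <- rowSums(Xr^2)
    Gr <- Xi %*% t(Xr)
    D2 <- D2 + sqrt(pmax(0, outer(sq, sqr, "+") - 2 * Gr))
  }
  D <- pmin(D1, D2) / np
  D <- (D + t(D)) / 2     # enforce exact symmetry against fp asymmetry
  diag(D) <- 0
  D
}
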