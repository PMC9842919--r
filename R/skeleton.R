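#' Build a white-matter skeleton from a mean FA map
#'
#' Registration-free ridge detection: a voxel belongs to the skeleton when
#' its mean FA is at least `threshold` (default 0.2, keeping the major
#' pathways and excluding peripheral tracts and grey matter) and it is a
#' local maximum along the discrete axis of strongest negative curvature of
#' the FA profile (the direction perpendicular to the sheet-like tract
#' center). That axis becomes the voxel's perpendicular search direction.
#'
#' @param mean_fa 3D numeric array of mean FA.
#' @param threshold Minimum FA for skeleton membership (default 0.2).
#' @return List of class `skeleton`: `mask` (logical 3D array) and
#'   `direction` (array `c(dim, 3)` of unit search directions; zero rows for
#'   non-skeleton voxels).
#' @export
build_skeleton <- function(mean_fa, threshold = 0.2) {
  d <- dim(mean_fa)
  if (length(d) != 3) stop("mean_fa must be a 3D array", call. = FALSE)
  mask <- array(FALSE, d)
  dirs <- array(0, c(d, 3))
  axes <- diag(3)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- mean_fa[i, j, k]
    if (is.na(v) || v < threshold) next
    best_curv <- 0; best_axis <- 0L; is_max <- FALSE
    for (ax in 1:3) {
      idx <- c(i, j, k)
      lo <- idx; lo[ax] <- lo[ax] - 1
      hi <- idx; hi[ax] <- hi[ax] + 1
      if (lo[ax] < 1 || hi[ax] > d[ax]) next
      f_lo <- mean_fa[lo[1], lo[2], lo[3]]
      f_hi <- mean_fa[hi[1], hi[2], hi[3]]
      if (is.na(f_lo) || is.na(f_hi)) next
      curv <- f_lo + f_hi - 2 * v      # discrete second derivative
      if (curv < best_curv) {
        best_curv <- curv; best_axis <- ax
        is_max <- v >= f_lo && v >= f_hi
      }
    }
    if (best_axis > 0L && is_max) {
      mask[i, j, k] <- TRUE
      dirs[i, j, k, ] <- axes[best_axis, ]
    }
  }
  structure(list(mask = mask, direction = dirs), class = "skeleton")
}

#' Construct a skeleton object from an explicit mask
#'
#' @param mask Logical 3D array.
#' @param direction Optional `c(dim, 3)` array of search directions; defaults
#'   to zero vectors (projection then keeps each voxel's own value).
#' @return A `skeleton` object.
#' @export
skeleton_from_mask <- function(mask, direction = NULL) {
  d <- dim(mask)
  if (is.null(direction)) direction <- array(0, c(d, 3))
  structure(list(mask = mask, direction = direction), class = "skeleton")
}

#' Project an FA map onto a skeleton
#'
#' Each skeleton voxel receives the maximum FA found by stepping up to
#' `search_cap` voxels in both senses of its perpendicular search direction
#' (including its own value). Voxels with a zero search direction keep their
#' own value. Non-skeleton voxels are NA in the output.
#'
#' The operation is idempotent on its own output restricted to the skeleton.
#'
#' @param fa_map 3D numeric array.
#' @param skeleton A `skeleton` object on the same grid.
#' @param search_cap Maximum search distance in voxels (default 5).
#' @return 3D array: projected FA on skeleton voxels, NA elsewhere.
#' @export
project_to_skeleton <- function(fa_map, skeleton, search_cap = 5L) {
  stopifnot(inherits(skeleton, "skeleton"))
  d <- dim(fa_map)
  if (!identical(d, dim(skeleton$mask))) {
    stop("fa_map and skeleton grids differ", call. = FALSE)
  }
  out <- array(NA_real_, d)
  idx <- which(skeleton$mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    dir <- skeleton$direction[v[1], v[2], v[3], ]
    best <- fa_map[v[1], v[2], v[3]]
    if (any(dir != 0)) {
      dir <- dir / sqrt(sum(dir^2))
      for (s in c(-(search_cap:1), 1:search_cap)) {
        p <- round(v + s * dir)
        if (any(p < 1) || any(p > d)) next
        val <- fa_map[p[1], p[2], p[3]]
        if (!is.na(val) && val > best) best <- val
      }
    }
    out[v[1], v[2], v[3]] <- best
  }
  out
}
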