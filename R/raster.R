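#' Define a voxel grid
#'
#' Axis-aligned grid with voxel-center convention: voxel `(i, j, k)`
#' (1-based in R) has its center at `origin + (index - 1) * spacing` and
#' covers the half-open box `[center - spacing/2, center + spacing/2)`.
#'
#' @param dim Integer length-3 voxel counts.
#' @param spacing Numeric length-3 voxel size in mm.
#' @param origin Numeric length-3 mm position of the first voxel center.
#' @return Object of class `voxel_grid`.
#' @export
voxel_grid <- function(dim, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim) != 3 || any(dim < 1)) {
    stop("dim must be three positive counts", call. = FALSE)
  }
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' Rasterize a tract into a voxel ROI
#'
#' Marks every voxel visited by any streamline: each polyline segment is
#' supersampled at a step of at most `step_frac` times the smallest voxel
#' dimension, and every sample is binned by the half-open voxel box it
#' falls into. Samples outside the grid are dropped with a warning.
#'
#' @param streamlines List of streamline point matrices (mm).
#' @param grid A [voxel_grid()].
#' @param step_frac Supersampling step as a fraction of the minimum voxel
#'   dimension (default 0.25).
#' @return List of class `tract_roi`: `mask` (logical 3D array),
#'   `voxel_volume` (mm^3), `grid`.
#' @export
rasterize_tract <- function(streamlines, grid, step_frac = 0.25) {
  stopifnot(inherits(grid, "voxel_grid"))
  step <- step_frac * min(grid$spacing)
  mask <- array(FALSE, grid$dim)
  dropped <- FALSE
  for (sl in streamlines) {
    sl <- as.matrix(sl)
    pts <- supersample_polyline(sl, step)
    # half-open boxes: voxel index i iff center_i - sp/2 <= x < center_i + sp/2
    idx <- floor(sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/") + 0.5) + 1
    inb <- idx[, 1] >= 1 & idx[, 1] <= grid$dim[1] &
           idx[, 2] >= 1 & idx[, 2] <= grid$dim[2] &
           idx[, 3] >= 1 & idx[, 3] <= grid$dim[3]
    if (any(!inb)) dropped <- TRUE
    idx <- idx[inb, , drop = FALSE]
    if (nrow(idx) > 0) {
      mask[idx] <- TRUE
    }
  }
  if (dropped) warning("streamline points outside grid were ignored",
                       call. = FALSE)
  structure(list(mask = mask, voxel_volume = prod(grid$spacing), grid = grid),
            class = "tract_roi")
}

supersample_polyline <- function(points, step) {
  n <- nrow(points)
  if (n == 1) return(points)
  out <- list(points[1, , drop = FALSE])
  for (s in seq_len(n - 1)) {
    a <- points[s, ]; b <- points[s + 1, ]
    len <- sqrt(sum((b - a)^2))
    m <- max(1L, ceiling(len / step))
    t <- seq_len(m) / m
    out[[s + 1]] <- cbind(a[1] + t * (b[1] - a[1]),
                          a[2] + t * (b[2] - a[2]),
                          a[3] + t * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

#' Tract volume from a voxel ROI
#'
#' Number of set voxels times the voxel volume.
#'
#' @param roi A `tract_roi`.
#' @return Volume in mm^3.
#' @export
tract_volume <- function(roi) {
  stopifnot(inherits(roi, "tract_roi"))
  sum(roi$mask) * roi$voxel_volume
}

#' Mean FA over a tract ROI
#'
#' Arithmetic mean of the FA map over the ROI's set voxels. An empty ROI is
#' undefined and returns `NA` with a warning (the subject/tract is excluded
#' case-wise downstream).
#'
#' @param roi A `tract_roi`.
#' @param fa_map 3D array on the same grid.
#' @return Mean FA (unitless) or `NA` for an empty ROI.
#' @export
tract_mean_fa <- function(roi, fa_map) {
  stopifnot(inherits(roi, "tract_roi"))
  if (!identical(dim(fa_map), dim(roi$mask))) {
    stop("fa_map and ROI grids differ", call. = FALSE)
  }
  if (!any(roi$mask)) {
    warning("empty ROI: mean FA undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(fa_map[roi$mask])
}
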