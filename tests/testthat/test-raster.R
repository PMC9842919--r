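test_that("axis-aligned streamline sets the voxels it crosses, once", {
  grid <- voxel_grid(c(5, 5, 5))
  sl <- cbind(c(0, 2), 0, 0)             # crosses voxels x = 0, 1, 2
  roi <- rasterize_tract(list(sl), grid)
  expect_equal(sum(roi$mask), 3)
  expect_true(all(roi$mask[1:3, 1, 1]))
  # duplicating the streamline changes nothing ("at least one" semantics)
  roi2 <- rasterize_tract(list(sl, sl), grid)
  expect_equal(roi2$mask, roi$mask)
})

test_that("rasterization matches a dense brute-force sampler", {
  set.seed(7)
  grid <- voxel_grid(c(12, 12, 12), spacing = c(1.5, 1.5, 1.5),
                     origin = c(0, 0, 0))
  t <- seq(0, 1, length.out = 40)
  sl <- cbind(14 * t + 1.3, 7 * sin(2 * pi * t) + 8, 10 * t^2 + 2)
  oracle_mask <- function(pts) {
    idx <- floor(sweep(sweep(pts, 2, grid$origin), 2,
                       grid$spacing, "/") + 0.5) + 1
    keep <- apply(idx, 1, function(v) all(v >= 1 & v <= 12))
    mask <- array(FALSE, grid$dim)
    mask[idx[keep, , drop = FALSE]] <- TRUE
    mask
  }
  fine <- oracle_mask(supersample_oracle(sl, 0.01))
  # at a matched 0.01 mm step the supersampler + binning reproduce the
  # independent dense rasterizer exactly
  roi_fine <- rasterize_tract(list(sl), grid, step_frac = 0.01 / 1.5)
  expect_equal(roi_fine$mask, fine)
  # the default quarter-voxel step never marks a voxel the curve misses
  roi <- rasterize_tract(list(sl), grid)
  expect_true(all(fine[roi$mask]))
  # any voxel it misses is one the curve only clips for less than one
  # sampling step (estimated from the dense 0.01 mm point counts)
  missed <- fine & !roi$mask
  if (any(missed)) {
    dense_pts <- supersample_oracle(sl, 0.01)
    idx <- floor(sweep(sweep(dense_pts, 2, grid$origin), 2,
                       grid$spacing, "/") + 0.5) + 1
    keep <- apply(idx, 1, function(v) all(v >= 1 & v <= 12))
    key <- idx[keep, , drop = FALSE]
    counts <- table(paste(key[, 1], key[, 2], key[, 3]))
    step <- 0.25 * 1.5
    for (v in which(missed)) {
      coords <- arrayInd(v, grid$dim)
      chord <- counts[paste(coords[1], coords[2], coords[3])] * 0.01
      expect_lt(as.numeric(chord), step)
    }
  }
})

test_that("out-of-grid points are dropped with a warning", {
  grid <- voxel_grid(c(3, 3, 3))
  sl <- cbind(c(-5, 1), 0, 0)
  expect_warning(roi <- rasterize_tract(list(sl), grid), "outside")
  expect_gt(sum(roi$mask), 0)
})

test_that("tract volume is count times voxel volume and monotone", {
  grid <- voxel_grid(c(10, 10, 10), spacing = c(0.9375, 0.9375, 2.5))
  sl1 <- cbind(seq(0, 3, by = 0.1) * 0.9375, 0, 0)
  roi1 <- rasterize_tract(list(sl1), grid)
  expect_equal(tract_volume(roi1),
               sum(roi1$mask) * 0.9375 * 0.9375 * 2.5)
  sl2 <- cbind(0, seq(0, 4, by = 0.1) * 0.9375, 0)
  roi12 <- rasterize_tract(list(sl1, sl2), grid)
  expect_gte(tract_volume(roi12), tract_volume(roi1))
  empty <- structure(list(mask = array(FALSE, c(2, 2, 2)), voxel_volume = 1,
                          grid = grid), class = "tract_roi")
  expect_equal(tract_volume(empty), 0)
})

test_that("rasterization is invariant to point and streamline order", {
  set.seed(15)
  grid <- voxel_grid(c(10, 10, 10))
  sls <- replicate(4, {
    t <- seq(0, 1, length.out = 20)
    cbind(8 * t + 0.5, 4 * sin(pi * t) + 2, 6 * t + 1)
  }, simplify = FALSE)
  a <- rasterize_tract(sls, grid)
  rev_pts <- lapply(sls, function(s) s[nrow(s):1, ])
  b <- rasterize_tract(rev(rev_pts), grid)
  expect_equal(a$mask, b$mask)
})

test_that("tract mean FA equals the masked average and respects bounds", {
  grid <- voxel_grid(c(4, 4, 4))
  mask <- array(FALSE, c(4, 4, 4)); mask[1, 1, 1] <- TRUE; mask[2, 1, 1] <- TRUE
  roi <- structure(list(mask = mask, voxel_volume = 1, grid = grid),
                   class = "tract_roi")
  fa <- array(0.4, c(4, 4, 4))
  expect_equal(tract_mean_fa(roi, fa), 0.4)
  fa[1, 1, 1] <- 0.3; fa[2, 1, 1] <- 0.5
  expect_equal(tract_mean_fa(roi, fa), 0.4)
  set.seed(2)
  fa_r <- array(runif(64), c(4, 4, 4))
  m <- tract_mean_fa(roi, fa_r)
  expect_equal(m, sum(fa_r[mask]) / 2)
  expect_gte(m, min(fa_r[mask])); expect_lte(m, max(fa_r[mask]))
  empty <- structure(list(mask = array(FALSE, c(4, 4, 4)), voxel_volume = 1,
                          grid = grid), class = "tract_roi")
  expect_warning(v <- tract_mean_fa(empty, fa), "empty")
  expect_true(is.na(v))
})
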