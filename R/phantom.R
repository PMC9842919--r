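#' Bundle geometry for a streamline phantom
#'
#' A geometric archetype of a white-matter tract: a 3D centerline (mm), a
#' dispersion radius and a streamline count.
#'
#' @param name Tract archetype name (see [tract_names()], or any label).
#' @param centerline Numeric matrix, one row per point, 3 columns (mm);
#'   at least 2 points.
#' @param radius Dispersion radius in mm, >= 0. Every generated streamline
#'   stays within this distance of the centerline pointwise.
#' @param n_streamlines Number of streamlines to generate, >= 1.
#' @return An object of class `bundle_geometry`.
#' @export
bundle_geometry <- function(name, centerline, radius = 2, n_streamlines = 100L) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2 || ncol(centerline) != 3) {
    stop("centerline must be an n x 3 matrix with n >= 2", call. = FALSE)
  }
  if (radius < 0) stop("radius must be non-negative", call. = FALSE)
  if (n_streamlines < 1) stop("n_streamlines must be >= 1", call. = FALSE)
  structure(list(name = name, centerline = centerline,
                 radius = radius, n_streamlines = as.integer(n_streamlines)),
            class = "bundle_geometry")
}

#' Built-in tract archetype centerlines
#'
#' Returns idealized centerlines (mm, in a roughly head-sized frame spanning
#' about 140 x 170 x 130 mm) for the 8 tract archetypes. These are geometric
#' stand-ins: an arch for the corpus callosum, a flatter arc above it for the
#' cingulum, a vertical curve for the corticospinal tract, fronto-occipital
#' arcs at different depths for SLF/ILF/IFO, a posterior sweep for the optic
#' radiation and a hook for the uncinate. They are mutually well separated so
#' clustering recovery on phantoms is well defined.
#'
#' @param n_points Points per centerline.
#' @return Named list of `n_points` x 3 matrices.
#' @export
tract_archetypes <- function(n_points = 50L) {
  t <- seq(0, 1, length.out = n_points)
  arc <- function(x, y, z) cbind(x, y, z)
  curves <- list(
    # midline arch, anterior-posterior
    CC  = arc(0, 140 * t - 70, 40 * sin(pi * t) + 30),
    # flatter arc above the callosum
    CG  = arc(8, 110 * t - 55, 28 * sin(pi * t) + 52),
    # lateral fronto-parietal arc
    SLF = arc(45, 120 * t - 60, 18 * sin(pi * t) + 38),
    # temporo-occipital, low and lateral
    ILF = arc(52, 110 * t - 75, 12 * sin(pi * t) - 5),
    # long fronto-occipital sweep, deeper than ILF
    IFO = arc(30, 150 * t - 80, 14 * sin(pi * t) + 12),
    # vertical, slight S-curve
    CST = arc(22 + 6 * sin(pi * t), 6 * sin(2 * pi * t) - 10, 110 * t - 45),
    # posterior radiation fanning back
    OR  = arc(38 - 18 * t, -30 - 55 * t, 18 * t + 8),
    # fronto-temporal hook
    UNC = arc(34, 45 * t + 8, 40 * (t - 0.55)^2 * 4 - 18)
  )
  lapply(curves, unname)
}

#' Generate a streamline bundle
#'
#' Each streamline is the centerline displaced by a smooth random offset
#' curve (a low-order Fourier perturbation plus a constant shift) scaled so
#' its maximum pointwise norm is at most `radius`. With probability 0.5 the
#' point order of a streamline is reversed, so downstream code must handle
#' orientation flips.
#'
#' @param geometry A [bundle_geometry()].
#' @param seed Integer seed.
#' @param flip_prob Probability of reversing a streamline's point order
#'   (default 0.5; set 0 for oriented output).
#' @return List of numeric point matrices (one streamline each), with the
#'   bundle name attached as attribute `"tract"`.
#' @export
generate_bundle <- function(geometry, seed = 1L, flip_prob = 0.5) {
  stopifnot(inherits(geometry, "bundle_geometry"))
  set.seed(seed)
  cl <- geometry$centerline
  np <- nrow(cl)
  t <- seq(0, 1, length.out = np)
  basis <- cbind(1, sin(pi * t), sin(2 * pi * t), cos(pi * t))
  out <- vector("list", geometry$n_streamlines)
  for (s in seq_len(geometry$n_streamlines)) {
    if (geometry$radius > 0) {
      coefs <- matrix(rnorm(ncol(basis) * 3), ncol(basis), 3)
      off <- basis %*% coefs
      maxnorm <- max(sqrt(rowSums(off^2)))
      scale <- geometry$radius * runif(1)^(1 / 3) /
        max(maxnorm, .Machine$double.eps)
      pts <- cl + off * scale
    } else {
      # draw the same variates so streamline k is seed-stable across radii
      rnorm(ncol(basis) * 3); runif(1)
      pts <- cl
    }
    if (runif(1) < flip_prob) pts <- pts[rev(seq_len(np)), , drop = FALSE]
    out[[s]] <- pts
  }
  attr(out, "tract") <- geometry$name
  out
}

#' Build a multi-subject phantom
#'
#' Generates all 8 archetype bundles for several synthetic subjects, applying
#' a small per-subject rigid jitter (translation) to emulate inter-individual
#' anatomy, and pools the streamlines with ground-truth labels.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param n_streamlines Streamlines per bundle per subject.
#' @param radius Bundle dispersion radius in mm.
#' @param subject_jitter_sd SD (mm) of the per-subject translation.
#' @param seed Integer seed.
#' @return List with `streamlines` (list of point matrices), `subject_id`
#'   (integer vector), `truth` (factor of tract names, ground-truth labels).
#' @export
build_phantom <- function(n_subjects = 3L, n_streamlines = 200L,
                          radius = 2, subject_jitter_sd = 1, seed = 1L) {
  arch <- tract_archetypes()
  set.seed(seed)
  shifts <- matrix(rnorm(n_subjects * 3, 0, subject_jitter_sd), n_subjects, 3)
  seeds <- sample.int(.Machine$integer.max, n_subjects * length(arch))
  streamlines <- list(); subject <- integer(0); truth <- character(0)
  k <- 0
  for (subj in seq_len(n_subjects)) {
    for (tr in names(arch)) {
      k <- k + 1
      geom <- bundle_geometry(tr, sweep(arch[[tr]], 2, shifts[subj, ], "+"),
                              radius = radius, n_streamlines = n_streamlines)
      sl <- generate_bundle(geom, seed = seeds[k])
      streamlines <- c(streamlines, sl)
      subject <- c(subject, rep(subj, length(sl)))
      truth <- c(truth, rep(tr, length(sl)))
    }
  }
  list(streamlines = streamlines, subject_id = subject,
       truth = factor(truth, levels = names(arch)))
}
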