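#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("labelings differ in length", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_i * sum_j / n2
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Study configuration
#'
#' All tunables of a seeded end-to-end synthetic study. A single master
#' seed deterministically derives per-stage seeds (counter-based), so stages
#' can be rerun independently and the whole run is byte-reproducible.
#'
#' @param cohort A [cohort_spec()] (its `seed` is overridden by the derived
#'   stage seed).
#' @param n_phantom_subjects Synthetic subjects in the clustering phantom.
#' @param n_streamlines Streamlines per bundle per phantom subject.
#' @param bundle_radius Phantom bundle dispersion radius (mm).
#' @param k Clusters per subset.
#' @param subset_size Streamlines per clustering subset.
#' @param repetitions Clustering repetitions.
#' @param stability_min Consensus pruning threshold.
#' @param voxel_spacing Rasterization voxel size (mm, length 3).
#' @param tolerance_ml ICV matching tolerance (ml).
#' @param alpha Significance level.
#' @param n_perm Permutations for the permutation test.
#' @param seed Master seed.
#' @return Object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_spec(n_men = 30L, n_women = 30L),
                         n_phantom_subjects = 3L, n_streamlines = 100L,
                         bundle_radius = 2, k = 8L, subset_size = 500L,
                         repetitions = 10L, stability_min = 0.5,
                         voxel_spacing = c(2, 2, 2), tolerance_ml = 10,
                         alpha = 0.05, n_perm = 500L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"))
  structure(as.list(environment()), class = "study_config")
}

# Counter-based seed derivation: small, independent, below 2^31.
stage_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 48271 + counter * 1000003) %% (2^31 - 2)) + 1L
}

#' Map consensus labels to named tracts
#'
#' Assigns each reference cluster representative to the nearest tract
#' archetype centerline (flip-invariant streamline distance), one-to-one
#' when cluster and archetype counts match (optimal assignment), otherwise
#' by nearest archetype.
#'
#' @param consensus A `consensus_segmentation` from [cluster_bundles()].
#' @param archetypes Named list of centerline matrices (default
#'   [tract_archetypes()]).
#' @return Named list mapping tract name to integer label set.
#' @export
labels_to_tracts <- function(consensus, archetypes = tract_archetypes()) {
  reps <- consensus$reference_reps
  np <- nrow(reps[[1]])
  arch <- lapply(archetypes, resample_streamline, n = np)
  k <- length(reps); m <- length(arch)
  cost <- matrix(0, k, m)
  for (i in seq_len(k)) for (j in seq_len(m)) {
    cost[i, j] <- streamline_distance(reps[[i]], arch[[j]])
  }
  if (k == m) {
    a <- solve_assignment(cost)
  } else {
    a <- apply(cost, 1, which.min)
  }
  sets <- lapply(seq_len(m), function(j) which(a == j))
  names(sets) <- names(arch)
  sets
}

#' Run a seeded end-to-end synthetic study
#'
#' Orchestrates the full replica: generate a covariate cohort; build a
#' multi-subject streamline phantom and segment it by consensus Ward
#' clustering; extract, rasterize and measure the named tracts; construct
#' ICV-matched pairs; and run the statistical layer (mean-centered
#' regressions with interaction screening, Benjamini-Hochberg family
#' correction, permutation inference with max-statistic correction, Cohen's
#' d, and the two-sample ICV t tests). Artifacts are written under
#' `out_dir` when given; a machine-readable summary is always returned.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory; created if missing.
#' @return List: `cohort` (subject table), `segmentation`, `tract_rois`,
#'   `tract_table` (phantom tract volumes and mean FA), `matched_pairs`,
#'   `stats` (per-tract regression report), `permutation`, `summary`
#'   (the JSON-ready study summary).
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  ms <- config$seed

  # stage 1: cohort
  spec <- config$cohort
  spec$seed <- stage_seed(ms, 1L)
  cohort <- generate_cohort(spec)

  # stage 2: phantom + consensus clustering
  phantom <- build_phantom(n_subjects = config$n_phantom_subjects,
                           n_streamlines = config$n_streamlines,
                           radius = config$bundle_radius,
                           seed = stage_seed(ms, 2L))
  seg <- cluster_bundles(phantom$streamlines, k = config$k,
                         subset_size = config$subset_size,
                         repetitions = config$repetitions,
                         seed = stage_seed(ms, 3L))
  ari <- adjusted_rand(seg$labels, as.integer(phantom$truth))

  # stage 3: tract extraction, rasterization, metrics
  tract_sets <- labels_to_tracts(seg)
  lo <- apply(do.call(rbind, lapply(phantom$streamlines, function(p)
    apply(p, 2, min))), 2, min) - 5
  hi <- apply(do.call(rbind, lapply(phantom$streamlines, function(p)
    apply(p, 2, max))), 2, max) + 5
  grid <- voxel_grid(dim = ceiling((hi - lo) / config$voxel_spacing) + 1,
                     spacing = config$voxel_spacing, origin = lo)
  # smooth synthetic FA field over the phantom frame for mean-FA extraction
  fa_field <- synth_fa_field(grid)
  rois <- list(); tract_rows <- list()
  for (tr in names(tract_sets)) {
    idx <- extract_tract(seg, tract_sets[[tr]],
                         stability_min = config$stability_min)
    if (length(idx) == 0) next
    roi <- rasterize_tract(phantom$streamlines[idx], grid)
    rois[[tr]] <- roi
    tract_rows[[tr]] <- data.frame(
      tract = tr, n_streamlines = length(idx),
      volume_mm3 = tract_volume(roi),
      mean_fa = tract_mean_fa(roi, fa_field),
      stringsAsFactors = FALSE)
  }
  tract_table <- do.call(rbind, tract_rows)
  rownames(tract_table) <- NULL

  # stage 4: ICV matching
  men <- cohort[cohort$sex == "M", ]
  women <- cohort[cohort$sex == "F", ]
  pairs <- match_by_icv(men, women, tolerance = config$tolerance_ml)

  # stage 5: statistics
  stats_tab <- tract_regression_report(cohort, alpha = config$alpha)
  fa_cols <- grep("_fa$", names(cohort), value = TRUE)
  Y <- t(as.matrix(cohort[, fa_cols, drop = FALSE]))
  design <- build_design(cohort)
  perm <- permutation_inference(Y, design, term = "icv_ml",
                                n_perm = config$n_perm, method = "maxstat",
                                seed = stage_seed(ms, 4L))
  t_whole <- two_sample_t(men$icv_ml, women$icv_ml)
  t_matched <- if (nrow(pairs) >= 2) {
    two_sample_t(pairs$icv_man, pairs$icv_woman)
  } else list(t = NA_real_, df = NA_real_, p = NA_real_)

  summary <- list(
    seed = ms,
    parameters = list(
      distance = "flip-invariant mean corresponding-point Euclidean",
      linkage = "ward (lance-williams, lowest-index tie-break)",
      k = config$k, subset_size = config$subset_size,
      repetitions = config$repetitions,
      stability_min = config$stability_min,
      tfce = list(H = 2, E = 0.5, dh = "max/100"),
      matching_tolerance_ml = config$tolerance_ml,
      alpha = config$alpha, n_perm = config$n_perm),
    cohort = list(n_men = spec$n_men, n_women = spec$n_women,
                  icv_t = t_whole$t, icv_p = t_whole$p),
    matched = list(n_pairs = nrow(pairs), icv_t = t_matched$t,
                   icv_p = t_matched$p),
    clustering = list(adjusted_rand = ari,
                      mean_stability = mean(seg$stability)),
    tracts = tract_table,
    permutation = list(term = "icv_ml",
                       min_p_corrected = min(perm$p_corrected))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_subject_table(cohort, file.path(out_dir, "cohort.csv"))
    write_segmentation(seg, phantom$subject_id,
                       file.path(out_dir, "segmentation.csv"))
    write.csv(tract_table, file.path(out_dir, "tract_metrics.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(pairs), file.path(out_dir, "matched_pairs.csv"),
              row.names = FALSE)
    write.csv(stats_tab, file.path(out_dir, "tract_stats.csv"),
              row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(cohort = cohort, segmentation = seg, tract_rois = rois,
       tract_table = tract_table, matched_pairs = pairs, stats = stats_tab,
       permutation = perm, summary = summary)
}

# Smooth synthetic FA field: plausible white-matter values (~0.3-0.45)
# varying gently across the frame.
synth_fa_field <- function(grid) {
  d <- grid$dim
  x <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  y <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  z <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  fx <- 0.05 * sin(x / 40)
  fy <- 0.04 * cos(y / 50)
  fz <- 0.03 * sin(z / 45)
  0.36 + outer(outer(fx, fy, "+"), fz, "+")
}

#' Per-tract regression report
#'
#' For each `<tract>_fa` column fits the mean-centered model
#' `fa ~ icv + age + sex` (after screening and dropping non-significant
#' interaction terms), collects the unstandardized coefficient, p value and
#' partial eta squared per effect family (ICV, age, sex), applies
#' Benjamini-Hochberg correction within each family across tracts, and adds
#' the women-minus-men Cohen's d per tract.
#'
#' @param cohort Subject table with `icv_ml`, `age`, `sex` and `_fa` columns.
#' @param alpha Significance level (default 0.05).
#' @return Data frame, one row per tract x family, with columns `tract`,
#'   `family`, `beta`, `p`, `p_adjusted`, `reject`, `eta_sq_partial`,
#'   `cohen_d`.
#' @export
tract_regression_report <- function(cohort, alpha = 0.05) {
  fa_cols <- grep("_fa$", names(cohort), value = TRUE)
  if (length(fa_cols) == 0) stop("no _fa columns in cohort", call. = FALSE)
  fam_term <- c(icv = "icv_ml", age = "age", sex = "sexF")
  rows <- list()
  for (col in fa_cols) {
    y <- cohort[[col]]
    scr <- interaction_screen(y, cohort, alpha = alpha)
    fit <- fit_glm(y, scr$design)
    ct <- fit$coefficients
    d_sex <- cohen_d(y[cohort$sex == "F"], y[cohort$sex == "M"])
    for (fam in names(fam_term)) {
      r <- ct[ct$term == fam_term[[fam]], ]
      rows[[length(rows) + 1]] <- data.frame(
        tract = sub("_fa$", "", col), family = fam,
        beta = r$beta, p = r$p, eta_sq_partial = r$eta_sq_partial,
        cohen_d = if (fam == "sex") d_sex else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  adj <- bh_correct(out$p, alpha = alpha, families = out$family)
  out$p_adjusted <- adj$p_adjusted
  out$reject <- adj$reject
  out[order(out$family, out$tract),
      c("tract", "family", "beta", "p", "p_adjusted", "reject",
        "eta_sq_partial", "cohen_d")]
}

#' Render per-family report tables
#'
#' Reshapes a [tract_regression_report()] into one table per effect family
#' with columns `tract`, `beta`, `p_adjusted`, `eta_sq_partial` (the layout
#' of a per-tract results table: regression coefficient, p value, effect
#' size). Missing families are omitted with a warning.
#'
#' @param stats A data frame from [tract_regression_report()].
#' @param families Families to render (default icv, sex, age).
#' @return Named list of data frames.
#' @export
render_report <- function(stats, families = c("icv", "sex", "age")) {
  out <- list()
  for (fam in families) {
    rows <- stats[stats$family == fam, , drop = FALSE]
    if (nrow(rows) == 0 && nrow(stats) > 0) {
      warning("family '", fam, "' missing from results", call. = FALSE)
      next
    }
    out[[fam]] <- rows[, c("tract", "beta", "p_adjusted", "eta_sq_partial",
                           if (fam == "sex") "cohen_d")]
  }
  out
}
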