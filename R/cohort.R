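#' Tract names used throughout the package
#'
#' Eight canonical white-matter tract archetypes: corpus callosum (CC),
#' cingulum (CG), superior longitudinal fasciculus (SLF), inferior
#' longitudinal fasciculus (ILF), inferior fronto-occipital fasciculus (IFO),
#' corticospinal tract (CST), optic radiation (OR) and uncinate fasciculus
#' (UNC). All but CC and CG are tracked per hemisphere, giving 14 analysis
#' units.
#'
#' @return Character vector of the 8 archetype names.
#' @export
tract_names <- function() {
  c("CC", "CG", "SLF", "ILF", "IFO", "CST", "OR", "UNC")
}

#' Hemisphere-split tract labels
#'
#' @return Character vector of the 14 per-hemisphere tract labels
#'   (CC and CG are midline; the other six get `_L`/`_R` suffixes).
#' @export
tract_labels <- function() {
  bilat <- c("SLF", "ILF", "IFO", "CST", "OR", "UNC")
  c("CC", "CG", as.vector(rbind(paste0(bilat, "_L"), paste0(bilat, "_R"))))
}

# Sex-averaged whole-group tract FA means, used as generator baselines.
default_tract_baselines <- function() {
  c(CC = 0.360, CG = 0.324,
    SLF_L = 0.3305, SLF_R = 0.3395,
    ILF_L = 0.3555, ILF_R = 0.3535,
    IFO_L = 0.3445, IFO_R = 0.3495,
    CST_L = 0.3915, CST_R = 0.3915,
    OR_L = 0.383, OR_R = 0.374,
    UNC_L = 0.3075, UNC_R = 0.3045)
}

#' Specify a synthetic cohort
#'
#' Bundles the parameters of the forward linear model used to generate
#' per-subject tract FA: sex-specific intracranial volume (ICV)
#' distributions, a uniform age window, per-tract FA baselines, and additive
#' ICV, age and sex effects with Gaussian residual noise.
#'
#' Default ICV distributions are 1667.9 +/- 120.2 ml for men and
#' 1455.9 +/- 115.8 ml for women; ages are uniform on 50-66 years. The ICV
#' slope default is 4.7e-5 FA per ml, the age slope -3.0e-4 FA per year, the
#' sex offset +0.004 FA for women, and the residual SD 0.011 FA.
#'
#' @param n_men,n_women Positive subject counts.
#' @param age_range Length-2 numeric, inclusive age window in years.
#' @param icv_mean_men,icv_sd_men,icv_mean_women,icv_sd_women ICV normal
#'   distribution parameters in ml; SDs must be positive.
#' @param tract_baselines Named numeric vector of per-tract baseline FA.
#' @param beta_icv FA change per ml of ICV (applied to centered ICV).
#' @param beta_age FA change per year of age (applied to centered age).
#' @param sex_offset FA added for women relative to men.
#' @param noise_sd Residual FA standard deviation, >= 0.
#' @param seed Integer seed; generation is fully reproducible given the spec.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_men = 383L, n_women = 429L,
                        age_range = c(50, 66),
                        icv_mean_men = 1667.9, icv_sd_men = 120.2,
                        icv_mean_women = 1455.9, icv_sd_women = 115.8,
                        tract_baselines = default_tract_baselines(),
                        beta_icv = 4.7e-5,
                        beta_age = -3.0e-4,
                        sex_offset = 0.004,
                        noise_sd = 0.011,
                        seed = 1L) {
  if (n_men < 1 || n_women < 1) {
    stop("n_men and n_women must be positive", call. = FALSE)
  }
  if (length(age_range) != 2 || diff(age_range) < 0) {
    stop("age_range must be an increasing (low, high) pair", call. = FALSE)
  }
  if (icv_sd_men <= 0 || icv_sd_women <= 0) {
    stop("ICV standard deviations must be positive", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (is.null(names(tract_baselines)) || any(!nzchar(names(tract_baselines)))) {
    stop("tract_baselines must be a named vector", call. = FALSE)
  }
  structure(list(
    n_men = as.integer(n_men), n_women = as.integer(n_women),
    age_range = as.numeric(age_range),
    icv_mean_men = icv_mean_men, icv_sd_men = icv_sd_men,
    icv_mean_women = icv_mean_women, icv_sd_women = icv_sd_women,
    tract_baselines = tract_baselines,
    beta_icv = beta_icv, beta_age = beta_age,
    sex_offset = sex_offset, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic subject table
#'
#' Runs the cohort model forward: draws sex-specific ICVs (truncated at zero),
#' uniform ages, and per-tract FA values
#' `baseline + beta_icv * (icv - mean(icv)) + beta_age * (age - mean(age)) +
#' sex_offset * [female] + N(0, noise_sd)`. Centering uses the realized cohort
#' means so that the generating betas are exactly the population slopes of the
#' fitted mean-centered regression.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` with columns `subject_id`, `sex` (`"M"`/`"F"`),
#'   `age`, `icv_ml` and one `<tract>_fa` column per tract baseline.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_men + spec$n_women
  sex <- c(rep("M", spec$n_men), rep("F", spec$n_women))
  icv <- c(rnorm(spec$n_men, spec$icv_mean_men, spec$icv_sd_men),
           rnorm(spec$n_women, spec$icv_mean_women, spec$icv_sd_women))
  # resample the (astronomically rare) non-positive draws
  while (any(icv <= 0)) {
    bad <- which(icv <= 0)
    men <- bad <= spec$n_men
    icv[bad] <- rnorm(length(bad),
                      ifelse(men, spec$icv_mean_men, spec$icv_mean_women),
                      ifelse(men, spec$icv_sd_men, spec$icv_sd_women))
  }
  age <- runif(n, spec$age_range[1], spec$age_range[2])
  female <- as.numeric(sex == "F")
  icv_c <- icv - mean(icv)
  age_c <- age - mean(age)

  out <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex = sex, age = age, icv_ml = icv,
    stringsAsFactors = FALSE
  )
  for (tr in names(spec$tract_baselines)) {
    eps <- if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else numeric(n)
    out[[paste0(tolower(tr), "_fa")]] <-
      spec$tract_baselines[[tr]] +
      spec$beta_icv * icv_c + spec$beta_age * age_c +
      spec$sex_offset * female + eps
  }
  out
}

#' Write / read a subject table
#'
#' CSV with header `subject_id,sex,age,icv_ml,<tract>_fa[,<tract>_vol_mm3]`;
#' sex coded `M`/`F`.
#'
#' @param table A subject `data.frame` as from [generate_cohort()].
#' @param path File path.
#' @return `read_subject_table` returns the `data.frame`;
#'   `write_subject_table` returns `path` invisibly.
#' @export
write_subject_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age", "icv_ml")
  if (!all(need %in% names(tab))) {
    stop("subject table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tab$sex %in% c("M", "F"))) {
    stop("sex must be coded M/F", call. = FALSE)
  }
  tab
}
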