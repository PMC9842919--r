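#' ICV-matched pair construction
#'
#' Pairs men and women whose intracranial volumes differ by less than
#' `tolerance` ml. Both lists are sorted by ICV and matched by dynamic
#' programming over non-crossing pairings, which (by the standard uncrossing
#' argument for threshold matching on a line) contains a maximum-cardinality
#' matching; among maximum matchings the one with the smallest total
#' absolute ICV difference is returned, so the matched groups are as close
#' in ICV as the data allow. Fully deterministic; tests verify the
#' cardinality against brute-force enumeration.
#'
#' @param men,women Data frames with columns `subject_id` and `icv_ml`.
#' @param tolerance Maximum absolute ICV difference in ml (exclusive;
#'   default 10).
#' @return Data frame of class `matched_pairs` with columns `man_id`,
#'   `woman_id`, `icv_man`, `icv_woman`; attribute `tolerance`.
#' @export
match_by_icv <- function(men, women, tolerance = 10) {
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  empty <- data.frame(man_id = character(0), woman_id = character(0),
                      icv_man = numeric(0), icv_woman = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(men) == 0 || nrow(women) == 0) {
    attr(empty, "tolerance") <- tolerance
    class(empty) <- c("matched_pairs", class(empty))
    return(empty)
  }
  if (any(men$icv_ml <= 0) || any(women$icv_ml <= 0)) {
    stop("ICVs must be positive", call. = FALSE)
  }
  m <- men[order(men$icv_ml, men$subject_id), ]
  w <- women[order(women$icv_ml, women$subject_id), ]
  nm <- nrow(m); nw <- nrow(w)
  # dp over (men 0..nm, women 0..nw): lexicographic (max pairs, min cost)
  npair <- matrix(0L, nm + 1, nw + 1)
  cost <- matrix(0, nm + 1, nw + 1)
  for (i in seq_len(nm)) {
    mi <- m$icv_ml[i]
    for (j in seq_len(nw)) {
      bp <- npair[i, j + 1]; bc <- cost[i, j + 1]       # skip man i
      if (npair[i + 1, j] > bp ||
          (npair[i + 1, j] == bp && cost[i + 1, j] < bc)) {
        bp <- npair[i + 1, j]; bc <- cost[i + 1, j]     # skip woman j
      }
      dij <- abs(mi - w$icv_ml[j])
      if (dij < tolerance) {
        pp <- npair[i, j] + 1L; pc <- cost[i, j] + dij  # pair (i, j)
        if (pp > bp || (pp == bp && pc < bc)) { bp <- pp; bc <- pc }
      }
      npair[i + 1, j + 1] <- bp
      cost[i + 1, j + 1] <- bc
    }
  }
  # backtrack (preferring pairing, then the move order used above)
  mi_idx <- integer(0); wi_idx <- integer(0)
  i <- nm; j <- nw
  while (i > 0 && j > 0) {
    dij <- abs(m$icv_ml[i] - w$icv_ml[j])
    if (dij < tolerance &&
        npair[i + 1, j + 1] == npair[i, j] + 1L &&
        abs(cost[i + 1, j + 1] - (cost[i, j] + dij)) < 1e-9) {
      mi_idx <- c(i, mi_idx); wi_idx <- c(j, wi_idx)
      i <- i - 1L; j <- j - 1L
    } else if (npair[i + 1, j + 1] == npair[i, j + 1] &&
               cost[i + 1, j + 1] == cost[i, j + 1]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  out <- data.frame(man_id = m$subject_id[mi_idx],
                    woman_id = w$subject_id[wi_idx],
                    icv_man = m$icv_ml[mi_idx], icv_woman = w$icv_ml[wi_idx],
                    stringsAsFactors = FALSE)
  attr(out, "tolerance") <- tolerance
  class(out) <- c("matched_pairs", class(out))
  out
}

#' Two-sample t statistic
#'
#' Student's pooled-variance t (default) or Welch's t, computed from raw
#' group vectors or from printed summary statistics (`n`, `mean`, `sd`),
#' so a reported t value can be reproduced from a paper's summary table.
#'
#' @param a,b Either numeric vectors (raw data) or lists
#'   `list(n =, mean =, sd =)`.
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  summ <- function(x) {
    if (is.list(x)) {
      list(n = x$n, mean = x$mean, sd = x$sd)
    } else {
      if (length(x) < 2) stop("need n >= 2 per group", call. = FALSE)
      list(n = length(x), mean = mean(x), sd = sd(x))
    }
  }
  s1 <- summ(a); s2 <- summ(b)
  if (s1$n < 2 || s2$n < 2) stop("need n >= 2 per group", call. = FALSE)
  if (variant == "pooled") {
    sp2 <- ((s1$n - 1) * s1$sd^2 + (s2$n - 1) * s2$sd^2) / (s1$n + s2$n - 2)
    if (sp2 == 0) {
      if (s1$mean == s2$mean) {
        return(list(t = 0, df = s1$n + s2$n - 2, p = 1))
      }
      stop("zero pooled SD with unequal means", call. = FALSE)
    }
    t <- (s1$mean - s2$mean) / sqrt(sp2 * (1 / s1$n + 1 / s2$n))
    df <- s1$n + s2$n - 2
  } else {
    se2 <- s1$sd^2 / s1$n + s2$sd^2 / s2$n
    if (se2 == 0) {
      if (s1$mean == s2$mean) return(list(t = 0, df = s1$n + s2$n - 2, p = 1))
      stop("zero standard error with unequal means", call. = FALSE)
    }
    t <- (s1$mean - s2$mean) / sqrt(se2)
    df <- se2^2 / (s1$sd^4 / (s1$n^2 * (s1$n - 1)) +
                   s2$sd^4 / (s2$n^2 * (s2$n - 1)))
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Cohen's d standardized mean difference
#'
#' `(mean_A - mean_B) / pooled SD`, with the pooled SD as in the
#' pooled-variance t test. Accepts raw vectors or printed summaries like
#' [two_sample_t()].
#'
#' @param a,b Numeric vectors or `list(n =, mean =, sd =)` summaries.
#' @return Cohen's d, or `NA` (with a warning) when the pooled SD is zero.
#' @export
cohen_d <- function(a, b) {
  summ <- function(x) {
    if (is.list(x)) x else list(n = length(x), mean = mean(x), sd = sd(x))
  }
  s1 <- summ(a); s2 <- summ(b)
  if (s1$n < 2 || s2$n < 2) stop("need n >= 2 per group", call. = FALSE)
  sp2 <- ((s1$n - 1) * s1$sd^2 + (s2$n - 1) * s2$sd^2) / (s1$n + s2$n - 2)
  if (sp2 == 0) {
    warning("zero pooled SD: d undefined", call. = FALSE)
    return(NA_real_)
  }
  (s1$mean - s2$mean) / sqrt(sp2)
}
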