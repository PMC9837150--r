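#' Hedges' g standardized mean difference
#'
#' Cohen's d on the pooled standard deviation with the small-sample bias
#' correction J = 1 - 3 / (4(n1 + n2) - 9).
#'
#' @param m1,s1,n1 mean, SD and size of group 1 (e.g. patients).
#' @param m2,s2,n2 mean, SD and size of group 2 (e.g. controls).
#' @return list with `g`, `d`, `j`, `pooled_sd`, `band`
#'   (interpretation: |g| > 0.2 small, > 0.5 medium, > 0.8 large), and an
#'   `infinite_effect` flag when the pooled SD is zero with unequal means.
#' @export
hedges_g <- function(m1, s1, n1, m2, s2, n2) {
  if (s1 < 0 || s2 < 0) stop("SDs must be nonnegative")
  if (n1 + n2 <= 2) stop("need n1 + n2 > 2")
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  if (sp == 0) {
    if (m1 == m2) {
      return(list(g = 0, d = 0, j = j, pooled_sd = 0,
                  band = "negligible", infinite_effect = FALSE))
    }
    return(list(g = sign(m1 - m2) * Inf, d = sign(m1 - m2) * Inf, j = j,
                pooled_sd = 0, band = "large", infinite_effect = TRUE))
  }
  d <- (m1 - m2) / sp
  g <- j * d
  list(g = g, d = d, j = j, pooled_sd = sp, band = effect_band(g),
       infinite_effect = FALSE)
}

#' Interpretation band for a standardized effect size
#'
#' @param g Hedges' g (sign ignored).
#' @return `"negligible"`, `"small"`, `"medium"` or `"large"`.
#' @export
effect_band <- function(g) {
  a <- abs(g)
  if (a > 0.8) "large" else if (a > 0.5) "medium"
  else if (a > 0.2) "small" else "negligible"
}

#' Percent difference between patient and control group means
#'
#' @param m_pat,m_ctl group means; `m_ctl` must be nonzero.
#' @return `100 * (m_pat - m_ctl) / m_ctl`.
#' @export
percent_diff <- function(m_pat, m_ctl) {
  if (any(m_ctl == 0)) stop("control mean must be nonzero")
  100 * (m_pat - m_ctl) / m_ctl
}

#' Resting energy expenditure by the Weir equation
#'
#' REE (kcal/day) = 1.44 x (3.94 x VO2 + 1.11 x VCO2), with VO2 and VCO2 in
#' mL/min. When a body mass is supplied the result is returned per kg.
#'
#' @param vo2,vco2 gas exchange rates, mL/min, nonnegative.
#' @param body_mass_kg optional body mass for a per-kg value.
#' @return kcal/day (or kcal/day/kg).
#' @export
weir_ree <- function(vo2, vco2, body_mass_kg = NULL) {
  if (any(vo2 < 0) || any(vco2 < 0)) stop("VO2/VCO2 must be nonnegative")
  ree <- 1.44 * (3.94 * vo2 + 1.11 * vco2)
  if (!is.null(body_mass_kg)) ree <- ree / body_mass_kg
  ree
}

#' Pool cohort-level effects
#'
#' Cohorts are pooled with equal weight: the summary effect is the
#' unweighted mean of cohort-level percent differences, tested against zero
#' with a one-sample t-test, or a paired t-test on (patient, control)
#' cohort-mean pairs.
#'
#' @param percent_diffs per-cohort percent differences (for
#'   `"one_sample_t"`), or `NULL` when `pairs` is given.
#' @param pairs optional two-column matrix/data.frame of (patient, control)
#'   cohort means (for `"paired_t"`).
#' @param test `"one_sample_t"` or `"paired_t"`.
#' @return list with `mean_percent_diff` (or mean paired difference), `t`,
#'   `p`, `n_cohorts`.
#' @export
pool_cohorts <- function(percent_diffs = NULL, pairs = NULL,
                         test = c("one_sample_t", "paired_t")) {
  test <- match.arg(test)
  if (test == "one_sample_t") {
    x <- percent_diffs
    if (length(x) < 2) stop("need at least 2 cohorts")
    if (stats::sd(x) == 0) {
      tt <- list(statistic = if (mean(x) == 0) 0 else Inf * sign(mean(x)),
                 p.value = if (mean(x) == 0) 1 else 0)
    } else {
      t0 <- stats::t.test(x, mu = 0)
      tt <- list(statistic = unname(t0$statistic), p.value = t0$p.value)
    }
    list(mean_percent_diff = mean(x), t = tt$statistic, p = tt$p.value,
         n_cohorts = length(x))
  } else {
    pairs <- as.matrix(pairs)
    if (nrow(pairs) < 2) stop("need at least 2 cohorts")
    d <- pairs[, 1] - pairs[, 2]
    if (stats::sd(d) == 0) {
      tt <- list(statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                 p.value = if (mean(d) == 0) 1 else 0)
    } else {
      t0 <- stats::t.test(pairs[, 1], pairs[, 2], paired = TRUE)
      tt <- list(statistic = unname(t0$statistic), p.value = t0$p.value)
    }
    list(mean_paired_diff = mean(d), t = tt$statistic, p = tt$p.value,
         n_cohorts = nrow(pairs))
  }
}

#' Consistency of Weir-derived REE and VO2 percent differences
#'
#' Elementwise difference (REE\% - VO2\%) across matched cohorts, with its
#' mean and range, to check that the two REE proxies agree.
#'
#' @param ree_pct,vo2_pct matched per-cohort percent differences.
#' @return list with `diffs`, `mean`, `range`.
#' @export
weir_consistency <- function(ree_pct, vo2_pct) {
  if (length(ree_pct) != length(vo2_pct)) stop("cohorts must be matched")
  d <- ree_pct - vo2_pct
  list(diffs = d, mean = mean(d), range = range(d))
}

#' Effect sizes for a cohort outcome table
#'
#' Computes the percent difference for every row and Hedges' g where both
#' SDs are available (rows with missing variance report only the percent
#' difference, mirroring aggregate-only source cohorts).
#'
#' @param cohorts data.frame with columns `cohort`, `outcome`, `mean_pat`,
#'   `sd_pat`, `n_pat`, `mean_ctl`, `sd_ctl`, `n_ctl` (SDs may be `NA`).
#' @return the input with `percent_diff`, `hedges_g`, `band` columns added.
#' @export
cohort_effects <- function(cohorts) {
  n <- nrow(cohorts)
  pd <- numeric(n); g <- rep(NA_real_, n); band <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    pd[i] <- percent_diff(cohorts$mean_pat[i], cohorts$mean_ctl[i])
    if (!is.na(cohorts$sd_pat[i]) && !is.na(cohorts$sd_ctl[i])) {
      h <- hedges_g(cohorts$mean_pat[i], cohorts$sd_pat[i], cohorts$n_pat[i],
                    cohorts$mean_ctl[i], cohorts$sd_ctl[i], cohorts$n_ctl[i])
      g[i] <- h$g
      band[i] <- h$band
    }
  }
  cohorts$percent_diff <- pd
  cohorts$hedges_g <- g
  cohorts$band <- band
  cohorts
}
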