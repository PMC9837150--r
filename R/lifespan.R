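#' Population doublings from one passage
#'
#' Doublings are computed from all harvested cells (live + dead), so cells
#' that divided and then died still count toward replicative age. Negative
#' doublings (population shrinkage) are retained, never truncated.
#'
#' @param cells_plated cells plated at the start of the interval (> 0).
#' @param live_harvested,dead_harvested cells recovered at passage
#'   (live + dead must be > 0).
#' @param interval_days days since the previous passage (> 0).
#' @return list with `pd` (population doublings, log2 of expansion) and
#'   `division_rate` (doublings/day).
#' @export
population_doubling <- function(cells_plated, live_harvested,
                                dead_harvested = 0, interval_days) {
  if (!is.finite(cells_plated) || cells_plated <= 0) {
    stop("cells_plated must be > 0")
  }
  harvested <- live_harvested + dead_harvested
  if (!is.finite(harvested) || harvested <= 0) {
    stop("live + dead harvested must be > 0")
  }
  if (!is.finite(interval_days) || interval_days <= 0) {
    stop("interval_days must be > 0")
  }
  pd <- log2(harvested / cells_plated)
  list(pd = pd, division_rate = pd / interval_days)
}

#' Build a lifespan trajectory from a passage log
#'
#' @param records data.frame with columns `day`, `cells_plated`,
#'   `live_harvested`, `dead_harvested` (optional, default 0) and optionally
#'   `donor`, `group`, `mean_cell_volume`. `day` is the harvest day; the
#'   first record's interval is measured from `day0` (default 0).
#' @param day0 culture start day for the first interval.
#' @return data.frame of class `lifespan_trajectory` with per-passage `pd`,
#'   `division_rate`, and running `cumulative_pd`.
#' @export
build_trajectory <- function(records, day0 = 0) {
  if (nrow(records) == 0) stop("no passage records")
  if (is.unsorted(records$day, strictly = TRUE)) {
    stop("passage days must be strictly increasing")
  }
  if (is.null(records$dead_harvested)) records$dead_harvested <- 0
  prev_day <- c(day0, records$day[-nrow(records)])
  interval <- records$day - prev_day
  res <- mapply(function(p, l, d, it) {
    unlist(population_doubling(p, l, d, it))
  }, records$cells_plated, records$live_harvested, records$dead_harvested,
     interval)
  records$interval_days <- interval
  records$pd <- res["pd", ]
  records$division_rate <- res["division_rate", ]
  records$cumulative_pd <- cumsum(records$pd)
  class(records) <- c("lifespan_trajectory", class(records))
  records
}

#' Hayflick limit of a lifespan trajectory
#'
#' Two termination rules are available:
#' \describe{
#'   \item{`"rate"` (default)}{total population doublings achieved before
#'     the division rate stays below `rate_threshold` (default 0.01
#'     divisions/day) for at least `consecutive` passages; the limit is the
#'     cumulative PD at the second (last required) such passage.}
#'   \item{`"window"`}{first passage at which fewer than `min_pd` doublings
#'     accumulated over the preceding `window_days` (default: < 1 doubling
#'     over 30 days).}
#' }
#' A trajectory that never terminates is censored at its final cumulative
#' doubling count (a status, not an error).
#'
#' @param traj a [build_trajectory()] result.
#' @param rule `"rate"` or `"window"`.
#' @param rate_threshold divisions/day threshold for rule `"rate"`.
#' @param consecutive passages required below threshold.
#' @param window_days,min_pd parameters of rule `"window"`.
#' @return list with `status` (`"terminated"`/`"censored"`), `hayflick_pd`,
#'   and `day` of termination (or last day when censored).
#' @export
hayflick_limit <- function(traj, rule = c("rate", "window"),
                           rate_threshold = 0.01, consecutive = 2,
                           window_days = 30, min_pd = 1) {
  rule <- match.arg(rule)
  n <- nrow(traj)
  idx <- NA_integer_
  if (rule == "rate") {
    below <- traj$division_rate < rate_threshold
    run <- 0
    for (i in seq_len(n)) {
      run <- if (below[i]) run + 1 else 0
      if (run >= consecutive) { idx <- i; break }
    }
  } else {
    for (i in seq_len(n)) {
      j <- which(traj$day <= traj$day[i] - window_days)
      if (length(j) == 0) next
      j <- max(j)
      if (traj$cumulative_pd[i] - traj$cumulative_pd[j] < min_pd) {
        idx <- i
        break
      }
    }
  }
  if (is.na(idx)) {
    list(status = "censored", hayflick_pd = traj$cumulative_pd[n],
         day = traj$day[n])
  } else {
    list(status = "terminated", hayflick_pd = traj$cumulative_pd[idx],
         day = traj$day[idx])
  }
}

#' Windowed group contrast of a longitudinal marker
#'
#' Group means use two-stage averaging: each donor's marker values inside
#' the window are averaged first, then donors are averaged with equal
#' weight, so densely sampled donors do not dominate. The percent
#' difference is relative to the control mean; the standardized effect is
#' Hedges' g computed on the donor-level means.
#'
#' @param data long data.frame with columns `donor`, `group`, `day`,
#'   `value`.
#' @param treat,ctrl group labels to contrast.
#' @param window numeric length-2 `[day_lo, day_hi]` (inclusive).
#' @return list with `window`, donor-level means, `mean_treat`, `mean_ctrl`,
#'   `percent_diff`, `hedges_g`.
#' @export
window_contrast <- function(data, treat, ctrl, window = c(20, 150)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  d <- data[data$day >= window[1] & data$day <= window[2] &
              data$group %in% c(treat, ctrl), , drop = FALSE]
  if (nrow(d) == 0) stop("no observations inside the analysis window")
  donor_means <- stats::aggregate(value ~ donor + group, data = d, FUN = mean)
  mt <- donor_means$value[donor_means$group == treat]
  mc <- donor_means$value[donor_means$group == ctrl]
  if (length(mt) == 0 || length(mc) == 0) {
    stop("both groups need at least one donor inside the window")
  }
  g <- if (length(mt) >= 2 && length(mc) >= 2) {
    hedges_g(mean(mt), stats::sd(mt), length(mt),
             mean(mc), stats::sd(mc), length(mc))$g
  } else {
    NA_real_
  }
  list(window = window, donor_means = donor_means,
       mean_treat = mean(mt), mean_ctrl = mean(mc),
       percent_diff = 100 * (mean(mt) - mean(mc)) / mean(mc),
       hedges_g = g)
}

#' Mixed-effects group test for a longitudinal marker
#'
#' Fits `value ~ group + day + (1 | donor)` by maximum likelihood and tests
#' the group effect with a likelihood-ratio comparison against the null
#' model lacking `group`. The chi-square reference is asymptotic in the
#' number of donors; with very few donors per group the test is
#' anti-conservative.
#'
#' @param data long data.frame with columns `donor`, `group`, `day`,
#'   `value`; `group` must have exactly 2 levels with at least 2 donors and
#'   3 timepoints per donor each.
#' @return list with `estimate` (group fixed effect), `se`, `p` (LRT),
#'   `converged`, and the fitted models.
#' @export
lmm_group_test <- function(data) {
  data$group <- factor(data$group)
  if (nlevels(data$group) != 2) stop("group must have exactly 2 levels")
  per_group_donors <- tapply(data$donor, data$group,
                             function(d) length(unique(d)))
  if (any(per_group_donors < 2)) {
    stop("each group needs at least 2 donors")
  }
  per_donor_tp <- tapply(data$day, data$donor, function(d) length(unique(d)))
  if (any(per_donor_tp < 3)) {
    stop("each donor needs at least 3 timepoints")
  }
  full <- lme4::lmer(value ~ group + day + (1 | donor), data = data,
                     REML = FALSE)
  null <- lme4::lmer(value ~ day + (1 | donor), data = data, REML = FALSE)
  lrt <- stats::anova(null, full)
  msgs <- full@optinfo$conv$lme4$messages
  co <- summary(full)$coefficients
  grow <- grep("^group", rownames(co))
  list(estimate = co[grow, "Estimate"], se = co[grow, "Std. Error"],
       p = lrt$`Pr(>Chisq)`[2],
       converged = is.null(msgs),
       full = full, null = null)
}

#' Mixed-effects tests across a batch of markers with FDR adjustment
#'
#' Applies [lmm_group_test()] per marker and adjusts the likelihood-ratio
#' p-values across the batch by Benjamini-Hochberg.
#'
#' @param data long data.frame with columns `marker`, `donor`, `group`,
#'   `day`, `value`.
#' @return data.frame with one row per marker: `estimate`, `se`, `p`, `q`,
#'   `converged` (markers whose fit fails carry `NA` and a status, never a
#'   silent fallback).
#' @export
lmm_marker_batch <- function(data) {
  markers <- unique(data$marker)
  rows <- lapply(markers, function(m) {
    res <- tryCatch(lmm_group_test(data[data$marker == m, , drop = FALSE]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(marker = m, estimate = NA_real_, se = NA_real_,
                 p = NA_real_, converged = FALSE,
                 status = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(marker = m, estimate = res$estimate, se = res$se,
                 p = res$p, converged = res$converged,
                 status = "ok", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Polynomial trajectory fit with data-driven order selection
#'
#' Default cubic; a fifth-order fit is adopted only when at least 8 points
#' are available and it lowers the small-sample-corrected AIC (AICc).
#'
#' @param x,y trajectory coordinates.
#' @param order `NULL` for automatic choice, otherwise 3 or 5.
#' @return list with `order`, `coefficients` (ascending powers), `fitted`,
#'   `residuals`, `aicc`, and the `lm` fit.
#' @export
fit_trajectory_polynomial <- function(x, y, order = NULL) {
  fit_one <- function(k) {
    n <- length(x)
    if (n <= k + 1) stop(sprintf("order-%d fit needs more than %d points",
                                 k, k + 1))
    fit <- stats::lm(y ~ poly(x, k, raw = TRUE))
    npar <- k + 2  # coefficients + residual variance
    aicc <- stats::AIC(fit) + 2 * npar * (npar + 1) / (n - npar - 1)
    list(order = k, coefficients = unname(stats::coef(fit)),
         fitted = unname(stats::fitted(fit)),
         residuals = unname(stats::residuals(fit)),
         aicc = aicc, fit = fit)
  }
  if (!is.null(order)) {
    if (!order %in% c(3, 5)) stop("order must be 3 or 5")
    return(fit_one(order))
  }
  f3 <- fit_one(3)
  if (length(x) >= 8) {
    f5 <- tryCatch(fit_one(5), error = function(e) NULL)
    if (!is.null(f5) && is.finite(f5$aicc) && f5$aicc < f3$aicc) return(f5)
  }
  f3
}

#' Linear rate of change of a marker
#'
#' Ordinary least-squares slope of `y` on `x`, optionally restricted to an
#' `x` window. Used e.g. for telomere attrition per population doubling or
#' epigenetic age per day.
#'
#' @param x predictor (population doublings or days).
#' @param y marker values.
#' @param window optional length-2 inclusive `x` range.
#' @return list with `slope`, `intercept`, `n`, `window`.
#' @export
slope_rate <- function(x, y, window = NULL) {
  if (!is.null(window)) {
    keep <- x >= window[1] & x <= window[2]
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 2) stop("slope needs at least 2 in-window points")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(x), window = window)
}

#' Relative change of a rate versus control
#'
#' `100 * (slope_treat - slope_ctrl) / slope_ctrl`: positive values mean the
#' process runs faster in the treated group (e.g. +162\% = 2.62-fold faster
#' attrition), regardless of the slopes' common sign.
#'
#' @param slope_treat,slope_ctrl fitted slopes; `slope_ctrl` must be
#'   nonzero.
#' @return percent change in rate.
#' @export
rate_ratio <- function(slope_treat, slope_ctrl) {
  if (!is.finite(slope_ctrl) || slope_ctrl == 0) {
    stop("rate_ratio undefined for a zero control slope")
  }
  100 * (slope_treat - slope_ctrl) / slope_ctrl
}

#' Normalize a raw amount to a per-cell value
#'
#' @param amount raw measured amount (e.g. pg of cytokine in the media).
#' @param cell_count cells at the time of sampling (> 0).
#' @param undetectable how a non-detected (`NA`) amount propagates:
#'   `"missing"` (default) keeps `NA`; `"zero"` substitutes 0, used only for
#'   analytes where absence is interpreted as true zero (e.g. GDF15 ELISA).
#' @return amount per cell.
#' @export
per_cell_normalize <- function(amount, cell_count,
                               undetectable = c("missing", "zero")) {
  undetectable <- match.arg(undetectable)
  if (any(!is.finite(cell_count)) || any(cell_count <= 0)) {
    stop("cell_count must be > 0")
  }
  if (undetectable == "zero") amount[is.na(amount)] <- 0
  amount / cell_count
}
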