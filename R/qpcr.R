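#' Triplicate Ct quality-control ladder
#'
#' Three steps, applied in order and all recorded as flags so a reported
#' mean can always be traced to the replicates it used:
#' \enumerate{
#'   \item Ct values above `hard_ct_max` (default 33) are discarded.
#'   \item If the surviving replicates' coefficient of variation (SD/mean of
#'     Ct) exceeds `cv_inspect` (default 0.02), the set is inspected for an
#'     outlier: a value lying more than `sd_mult` (default 2) standard
#'     deviations from the mean of the \emph{other} replicates is removed
#'     (at most one, the most extreme), keeping the remaining duplicate.
#'   \item If the final CV still exceeds `cv_reject` (default 0.1) the
#'     sample is rejected.
#' }
#'
#' @param ct numeric vector of up to 3 cycle-threshold values.
#' @param hard_ct_max absolute Ct cutoff.
#' @param cv_inspect CV above which the triplicate is inspected.
#' @param cv_reject CV above which the sample is rejected.
#' @param sd_mult outlier distance in leave-one-out standard deviations.
#' @return list with `mean_ct` (`NA` when rejected), `ct_used`, `rejected`,
#'   `flags` (cumulative across steps), `reason` when rejected.
#' @export
triplicate_qc <- function(ct, hard_ct_max = 33, cv_inspect = 0.02,
                          cv_reject = 0.1, sd_mult = 2) {
  ct <- ct[is.finite(ct)]
  if (length(ct) == 0) {
    return(list(mean_ct = NA_real_, ct_used = numeric(0), rejected = TRUE,
                flags = "no_finite_ct", reason = "no finite Ct values"))
  }
  if (any(ct <= 0)) stop("Ct values must be positive")
  flags <- character(0)

  high <- ct > hard_ct_max
  if (any(high)) {
    flags <- c(flags, sprintf("ct_above_%g_discarded", hard_ct_max))
    ct <- ct[!high]
  }
  if (length(ct) == 0) {
    return(list(mean_ct = NA_real_, ct_used = numeric(0), rejected = TRUE,
                flags = flags, reason = "all Ct above hard cutoff"))
  }

  cv <- function(x) if (length(x) > 1) stats::sd(x) / mean(x) else 0
  if (cv(ct) > cv_inspect && length(ct) >= 3) {
    flags <- c(flags, "cv_inspected")
    # leave-one-out z score: distance from the mean of the other replicates
    z <- vapply(seq_along(ct), function(i) {
      others <- ct[-i]
      s <- stats::sd(others)
      if (s == 0) return(if (ct[i] != mean(others)) Inf else 0)
      abs(ct[i] - mean(others)) / s
    }, numeric(1))
    if (any(z > sd_mult)) {
      worst <- which.max(z + abs(ct - mean(ct)) * 1e-9)
      flags <- c(flags, "outlier_removed")
      ct <- ct[-worst]
    }
  }

  final_cv <- cv(ct)
  if (final_cv > cv_reject) {
    return(list(mean_ct = NA_real_, ct_used = ct, rejected = TRUE,
                flags = c(flags, "cv_reject"),
                reason = sprintf("final CV %.3f > %.3f", final_cv, cv_reject)))
  }
  list(mean_ct = mean(ct), ct_used = ct, rejected = FALSE, flags = flags,
       reason = NULL)
}

#' mtDNA copy number by the delta-Ct method
#'
#' `delta_ct = Ct_nuclear - Ct_mito`; copies per cell = `2^delta_ct * 2`,
#' the factor 2 accounting for the diploid nuclear reference genome.
#'
#' @param mean_ct_mt mean Ct of the mitochondrial amplicon (e.g. ND1).
#' @param mean_ct_nuc mean Ct of the nuclear amplicon (e.g. B2M).
#' @return mtDNA copies per cell, or `NA` if either input is `NA` (e.g. a
#'   QC-rejected triplicate).
#' @export
mtdna_copy_number <- function(mean_ct_mt, mean_ct_nuc) {
  if (is.na(mean_ct_mt) || is.na(mean_ct_nuc)) return(NA_real_)
  2^(mean_ct_nuc - mean_ct_mt) * 2
}

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct against log10(quantity) over serial dilutions of
#' a reference DNA. Amplification efficiency is `10^(-1/slope) - 1`
#' (1.0 = perfect doubling per cycle).
#'
#' @param quantity known input quantities (same unit as later estimates).
#' @param ct observed Ct values.
#' @return object of class `standard_curve` with `slope`, `intercept`,
#'   `efficiency`, `r_squared` and the standards' Ct range.
#' @export
fit_standard_curve <- function(quantity, ct) {
  if (length(quantity) != length(ct)) stop("quantity/ct length mismatch")
  if (length(quantity) < 3) stop("need at least 3 standards")
  lq <- log10(quantity)
  if (diff(range(lq)) < 2) stop("standards must span at least 2 log10 units")
  fit <- stats::lm(ct ~ lq)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("invalid standard curve: slope must be negative")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ct - mean(ct))^2)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = 1 - ss_res / ss_tot,
                 ct_range = range(ct),
                 quantity_range = range(quantity)),
            class = "standard_curve")
}

#' Interpolate a quantity from a standard curve
#'
#' Inverts the fitted log-linear relation. Cts outside the standards' Ct
#' range are still converted but flagged as extrapolation.
#'
#' @param curve a [fit_standard_curve()] result.
#' @param ct observed Ct value(s).
#' @return list with `quantity` and logical `extrapolated`.
#' @export
interpolate_quantity <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  q <- 10^((ct - curve$intercept) / curve$slope)
  extrap <- ct < curve$ct_range[1] | ct > curve$ct_range[2]
  list(quantity = q, extrapolated = extrap)
}

# Dixon's Q critical values (ratio r10 = gap/range), two-sided
.dixon_critical <- data.frame(
  n = 3:7,
  alpha_0.10 = c(0.941, 0.765, 0.642, 0.560, 0.507),
  alpha_0.05 = c(0.970, 0.829, 0.710, 0.625, 0.568),
  alpha_0.01 = c(0.994, 0.926, 0.821, 0.740, 0.680)
)

#' Dixon's Q outlier test for small replicate sets
#'
#' Q = (gap between the suspect extreme and its nearest neighbour) / range.
#' The suspect value is removed iff Q exceeds the published critical value
#' for the sample size at the chosen significance level.
#'
#' @param values 3 to 7 numeric replicates.
#' @param alpha 0.10, 0.05 (default) or 0.01.
#' @return list with `outlier_index` (`NA` when none), `q`, `critical`.
#' @export
dixon_q <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3 || n > 7) stop("Dixon's Q implemented for 3-7 values")
  col <- paste0("alpha_", format(alpha, nsmall = 2))
  if (!col %in% names(.dixon_critical)) {
    stop("alpha must be one of 0.10, 0.05, 0.01")
  }
  crit <- .dixon_critical[[col]][.dixon_critical$n == n]
  s <- sort(values)
  rng <- s[n] - s[1]
  if (rng == 0) {
    return(list(outlier_index = NA_integer_, q = 0, critical = crit))
  }
  q_low <- (s[2] - s[1]) / rng
  q_high <- (s[n] - s[n - 1]) / rng
  if (max(q_low, q_high) > crit) {
    suspect <- if (q_high >= q_low) s[n] else s[1]
    idx <- which(values == suspect)[1]
    list(outlier_index = idx, q = max(q_low, q_high), critical = crit)
  } else {
    list(outlier_index = NA_integer_, q = max(q_low, q_high),
         critical = crit)
  }
}

#' Reconcile duplicate telomere T/S runs
#'
#' If the duplicate agrees with the initial run within `tolerance`
#' (default 7\%, relative to the initial run), the final value is their
#' mean. Otherwise a third run is required; the two closest values are kept
#' and their mean reported. With no third run available the sample stays
#' unresolved.
#'
#' @param run1,run2 initial and duplicate T/S values.
#' @param run3 optional third run.
#' @param tolerance maximum relative discrepancy.
#' @return list with `final` (`NA` when unresolved), `runs_used`, `status`
#'   (`"accepted"`, `"third_run"`, `"unresolved"`).
#' @export
reconcile_duplicate_runs <- function(run1, run2, run3 = NULL,
                                     tolerance = 0.07) {
  if (abs(run2 - run1) / run1 <= tolerance) {
    return(list(final = mean(c(run1, run2)), runs_used = c(run1, run2),
                status = "accepted"))
  }
  if (is.null(run3)) {
    return(list(final = NA_real_, runs_used = c(run1, run2),
                status = "unresolved"))
  }
  runs <- c(run1, run2, run3)
  pairs <- utils::combn(3, 2)
  gaps <- apply(pairs, 2, function(p) abs(runs[p[1]] - runs[p[2]]))
  best <- pairs[, which.min(gaps)]
  list(final = mean(runs[best]), runs_used = runs[best],
       status = "third_run")
}

#' Cell-free mitochondrial-to-nuclear DNA ratio
#'
#' @param mt_copies cf-mtDNA concentration (copies/uL).
#' @param nuc_copies cf-nDNA concentration (copies/uL), must be > 0.
#' @return mt/nuc ratio.
#' @export
cfdna_ratio <- function(mt_copies, nuc_copies) {
  if (any(nuc_copies <= 0)) stop("nuclear copies must be > 0")
  mt_copies / nuc_copies
}
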