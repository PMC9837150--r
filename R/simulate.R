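#' Derive a reproducible sub-stream seed
#'
#' One pseudo-random stream per generated object, derived from the master
#' seed and a label, so adding a generator never shifts the outputs of the
#' others.
#'
#' @param seed master seed (integer).
#' @param label stream label.
#' @return integer seed below 2^31.
#' @export
stream_seed <- function(seed, label) {
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u))
  as.integer((as.numeric(seed) %% 1e6 * 7919 + h * 104729) %% 2147483647L)
}

#' Scenario presets for the synthetic study
#'
#' Emulates the three arms of a longitudinal fibroblast lifespan study:
#' \describe{
#'   \item{`"control"`}{healthy donors; 64\% of ATP from OxPhos, division
#'     rate 0.5/day declining linearly over ~220 days (replicative limit
#'     near 55 doublings), telomere attrition -0.010 T/S per doubling,
#'     epigenetic aging 0.2 yr/day, ~400 mtDNA copies/cell.}
#'   \item{`"surf1"`}{SURF1-mutant-like: OxPhos fraction shifted to 23\%,
#'     total ATP demand 91\% above control (hypermetabolism), slower
#'     division and a replicative limit 53\% below control, telomere
#'     attrition accelerated by 162\% and epigenetic aging by 131\%.}
#'   \item{`"oligo"`}{chronic ATP-synthase-inhibition-like: OxPhos fraction
#'     10\%, total ATP demand doubled, replicative limit 40\% below
#'     control, telomere attrition accelerated by 769\% and epigenetic
#'     aging by 54\%.}
#' }
#'
#' @param name scenario name.
#' @return named list of ground-truth parameters.
#' @export
scenario_preset <- function(name = c("control", "surf1", "oligo")) {
  name <- match.arg(name)
  base_j <- 2000       # pmol ATP/min/well at 20,000 cells/well
  ctrl_hayflick <- 55  # doublings; r0 * lifespan_days / 2 for linear decline
  p <- switch(name,
    control = list(j_total = base_j, ox_fraction = 0.64,
                   r0 = 0.5, hayflick = ctrl_hayflick,
                   telomere_slope = -0.010, dnam_slope = 0.2,
                   mtdna_copies = 400),
    surf1 = list(j_total = base_j * 1.91, ox_fraction = 0.23,
                 r0 = 0.4, hayflick = ctrl_hayflick * (1 - 0.53),
                 telomere_slope = -0.010 * 2.62, dnam_slope = 0.2 * 2.31,
                 mtdna_copies = 600),
    oligo = list(j_total = base_j * 2.0, ox_fraction = 0.10,
                 r0 = 0.5, hayflick = ctrl_hayflick * (1 - 0.40),
                 telomere_slope = -0.010 * 8.69, dnam_slope = 0.2 * 1.54,
                 mtdna_copies = 450)
  )
  p$j_ox <- p$ox_fraction * p$j_total
  p$j_glyc <- p$j_total - p$j_ox
  p$lifespan_days <- 2 * p$hayflick / p$r0
  p$scenario <- name
  p
}

#' Simulate a MitoStress plate with known ATP-flux ground truth
#'
#' Inverts the flux equations: from a target (j_ox, j_glyc) pair it derives
#' the ATP-linked respiration, basal mitochondrial respiration (via the
#' configured proton-leak fraction), the non-mitochondrial floor and the
#' FCCP maximum, plus the basal ECAR implied by the glycolytic proton
#' efflux. Phase OCR/ECAR are constant within each phase; multiplicative
#' Gaussian noise is applied per measurement. At zero noise the analysis
#' chain recovers the truth exactly.
#'
#' @param truth list with `j_ox` and `j_glyc` (pmol ATP/min/well), e.g. a
#'   [scenario_preset()].
#' @param scheme an [injection_scheme()].
#' @param k a [stoichiometry_constants()] object.
#' @param n_wells wells to generate.
#' @param noise_sd multiplicative noise SD per measurement (0.05 = 5\%).
#' @param seed master seed.
#' @param leak_fraction proton leak as a fraction of basal mitochondrial
#'   respiration (1 - coupling efficiency).
#' @param nonmito_fraction non-mitochondrial OCR as a fraction of basal
#'   mitochondrial respiration.
#' @param maximal_ratio FCCP-uncoupled over basal mitochondrial respiration.
#' @param cell_count cells per well.
#' @param group,donor labels attached to the traces.
#' @return list with `traces` (list of [well_trace()]), `truth` (per-well
#'   ground-truth data.frame plus generator parameters), `seed`.
#' @export
simulate_plate <- function(truth, scheme = injection_scheme(),
                           k = stoichiometry_preset(),
                           n_wells = 10, noise_sd = 0.05, seed = 1,
                           leak_fraction = 0.2, nonmito_fraction = 0.15,
                           maximal_ratio = 2, cell_count = 20000,
                           group = truth$scenario %||% "group",
                           donor = "sim") {
  j_ox <- truth$j_ox
  j_glyc <- truth$j_glyc
  atp_linked <- j_ox / (2 * k$po_oxphos)
  basal_mito <- atp_linked / (1 - leak_fraction)
  ppr_glyc <- (j_glyc - k$glyc_ox_adjunct * basal_mito) / k$atp_per_lactate
  if (basal_mito <= 0 || ppr_glyc < 0) {
    stop("infeasible truth: implied respiration or glycolytic efflux <= 0")
  }
  nonmito <- nonmito_fraction * basal_mito
  phase_ocr <- c(basal = basal_mito + nonmito,
                 oligomycin = (basal_mito - atp_linked) + nonmito,
                 fccp = maximal_ratio * basal_mito + nonmito,
                 rot_aa = nonmito)
  ecar_basal <- (ppr_glyc + k$h_resp * basal_mito) * k$buffering_power

  set.seed(stream_seed(seed, paste0("plate:", group)))
  phase <- scheme_phase_index(scheme)
  time_min <- seq_len(scheme$n_total) * 6.5
  traces <- lapply(seq_len(n_wells), function(w) {
    ocr <- phase_ocr[phase]
    ecar <- rep(ecar_basal, scheme$n_total)
    if (noise_sd > 0) {
      ocr <- ocr * (1 + stats::rnorm(length(ocr), 0, noise_sd))
      ecar <- ecar * (1 + stats::rnorm(length(ecar), 0, noise_sd))
    }
    well_trace(well = sprintf("%s_w%02d", group, w), time_min = time_min,
               ocr = unname(ocr), ecar = ecar, cell_count = cell_count,
               group = group, donor = donor)
  })
  truth_df <- data.frame(
    well = vapply(traces, function(t) t$well, character(1)),
    j_ox = j_ox, j_glyc = j_glyc, j_total = j_ox + j_glyc,
    ox_fraction = j_ox / (j_ox + j_glyc),
    atp_linked = atp_linked, basal_mito = basal_mito,
    proton_leak = basal_mito - atp_linked, nonmito = nonmito,
    ppr_glyc = ppr_glyc, ecar_basal = ecar_basal,
    stringsAsFactors = FALSE
  )
  list(traces = traces,
       truth = list(per_well = truth_df, noise_sd = noise_sd, seed = seed,
                    leak_fraction = leak_fraction,
                    nonmito_fraction = nonmito_fraction,
                    maximal_ratio = maximal_ratio,
                    constants = k$name),
       seed = seed)
}

#' Simulate a declining-division-rate growth curve
#'
#' Division rate declines linearly, `r(t) = r0 * (1 - t / lifespan_days)`
#' (or logistically), crossing the 0.01 divisions/day termination threshold
#' at a computable cumulative doubling count. Per-passage doublings are
#' `r(midpoint) * interval`; harvested counts are derived from them
#' deterministically when `noise_sd = 0`, so rule-based Hayflick estimates
#' can be checked against the generator's own analytic value.
#'
#' @param r0 initial division rate, divisions/day.
#' @param lifespan_days day at which the linear rate reaches zero (or
#'   logistic midpoint when `decline = "logistic"`).
#' @param decline `"linear"` or `"logistic"`.
#' @param tau logistic time constant (days).
#' @param interval_days days between passages.
#' @param cells_plated cells plated each passage.
#' @param dead_fraction fraction of harvested cells dead.
#' @param noise_sd multiplicative lognormal noise SD on the per-passage
#'   doubling count (0 = deterministic). Doublings stay nonnegative, so
#'   noisy cumulative curves remain nondecreasing.
#' @param seed master seed.
#' @param label stream label (e.g. donor id).
#' @param max_days stop generating passages after this many days even if
#'   the termination rule was never met (the trajectory is then censored).
#' @return list with `records` (passage-log data.frame: `day`,
#'   `cells_plated`, `live_harvested`, `dead_harvested`) and `truth`
#'   (per-passage rates/doublings and the analytic rule-based Hayflick
#'   limit `hayflick_pd`).
#' @export
simulate_lifespan <- function(r0 = 0.5, lifespan_days = 220,
                              decline = c("linear", "logistic"), tau = 12,
                              interval_days = 5, cells_plated = 5e5,
                              dead_fraction = 0.02, noise_sd = 0,
                              seed = 1, label = "donor",
                              max_days = 5 * lifespan_days) {
  decline <- match.arg(decline)
  rate_fn <- switch(decline,
    linear = function(t) pmax(0, r0 * (1 - t / lifespan_days)),
    logistic = function(t) r0 / (1 + exp((t - lifespan_days) / tau))
  )
  # generate passages until the rate has been < 0.01/day for 3 passages
  days <- numeric(0); rates <- numeric(0)
  d <- 0; low_run <- 0
  while (low_run < 3 && d < max_days) {
    mid <- d + interval_days / 2
    d <- d + interval_days
    r <- rate_fn(mid)
    days <- c(days, d)
    rates <- c(rates, r)
    low_run <- if (r < 0.01) low_run + 1 else 0
  }
  pd <- rates * interval_days
  if (noise_sd > 0) {
    set.seed(stream_seed(seed, paste0("lifespan:", label)))
    pd <- pd * exp(stats::rnorm(length(pd), 0, noise_sd))
    rates <- pd / interval_days
  }
  cum_pd <- cumsum(pd)

  # analytic rule-A truth from the generator's own (possibly noisy) rates
  below <- rates < 0.01
  run <- 0; idx <- NA_integer_
  for (i in seq_along(below)) {
    run <- if (below[i]) run + 1 else 0
    if (run >= 2) { idx <- i; break }
  }
  harvested <- cells_plated * 2^pd
  records <- data.frame(
    day = days,
    cells_plated = cells_plated,
    live_harvested = harvested * (1 - dead_fraction),
    dead_harvested = harvested * dead_fraction
  )
  list(records = records,
       truth = list(rates = rates, pd = pd, cumulative_pd = cum_pd,
                    hayflick_pd = if (is.na(idx)) NA_real_ else cum_pd[idx],
                    termination_index = idx, r0 = r0,
                    lifespan_days = lifespan_days, decline = decline,
                    noise_sd = noise_sd, seed = seed))
}

#' Simulate qPCR plates with known copy numbers
#'
#' Cycle thresholds follow
#' `Ct = intercept - log2(quantity) / log2(1 + efficiency)` with additive
#' Gaussian noise, for a mitochondrial and a nuclear target on each sample
#' (nuclear quantity 1 per diploid genome, mitochondrial quantity
#' copies / 2), plus serial-dilution standards for both targets spanning 4
#' log10 units. The assay is emulated as duplex chemistry: both targets are
#' read from the same physical well, so the dominant (template/pipetting)
#' noise component `ct_noise_sd` is shared between targets within a well,
#' with a smaller independent per-channel component `channel_noise_sd` on
#' top. A configurable fraction of triplicates receives one late-shifted
#' outlier well to exercise the QC ladder.
#'
#' @param true_copies mtDNA copies per cell (recycled over samples).
#' @param n_samples number of samples.
#' @param efficiency amplification efficiency (1 = perfect doubling).
#' @param ct_noise_sd additive well-level Ct noise SD (shared by the two
#'   channels of a well).
#' @param channel_noise_sd additive channel-specific Ct noise SD.
#' @param intercept Ct at quantity 1.
#' @param outlier_frac fraction of triplicates given an outlier well.
#' @param outlier_shift Ct shift applied to outlier wells.
#' @param seed master seed.
#' @return list with `samples` (sample, target, well, ct), `standards`
#'   (target, quantity, ct, noise-free), and `truth`.
#' @export
simulate_qpcr <- function(true_copies = 400, n_samples = 10,
                          efficiency = 0.95, ct_noise_sd = 0.1,
                          channel_noise_sd = ct_noise_sd / 2,
                          intercept = 32, outlier_frac = 0,
                          outlier_shift = 5, seed = 1) {
  set.seed(stream_seed(seed, "qpcr"))
  copies <- rep_len(true_copies, n_samples)
  ct_of <- function(q) intercept - log2(q) / log2(1 + efficiency)
  rows <- list()
  for (i in seq_len(n_samples)) {
    well_noise <- stats::rnorm(3, 0, ct_noise_sd)
    for (target in c("mt", "nuc")) {
      q <- if (target == "mt") copies[i] / 2 else 1
      ct <- ct_of(q) + well_noise + stats::rnorm(3, 0, channel_noise_sd)
      is_out <- outlier_frac > 0 && stats::runif(1) < outlier_frac
      if (is_out) ct[3] <- ct[3] + outlier_shift
      rows[[length(rows) + 1]] <- data.frame(
        sample = sprintf("s%03d", i), target = target, well = 1:3, ct = ct,
        stringsAsFactors = FALSE
      )
    }
  }
  standards <- do.call(rbind, lapply(c("mt", "nuc"), function(tg) {
    q <- 10^seq(-2, 2, by = 1)
    data.frame(target = tg, quantity = q, ct = ct_of(q),
               stringsAsFactors = FALSE)
  }))
  list(samples = do.call(rbind, rows), standards = standards,
       truth = list(copies = copies, efficiency = efficiency,
                    intercept = intercept, ct_noise_sd = ct_noise_sd,
                    channel_noise_sd = channel_noise_sd,
                    outlier_frac = outlier_frac, seed = seed))
}

#' Recover mtDNA copy numbers from a simulated qPCR experiment
#'
#' Reference analysis route: triplicate QC per sample and target,
#' standard-curve interpolation of mean Cts to quantities, copies per cell
#' = 2 x (mitochondrial / nuclear quantity).
#'
#' @param sim a [simulate_qpcr()] result (or equivalently shaped tables).
#' @param ... passed to [triplicate_qc()].
#' @return data.frame with per-sample `copies` (`NA` when a triplicate was
#'   rejected) and QC rejection flags.
#' @export
recover_copy_numbers <- function(sim, ...) {
  curves <- lapply(split(sim$standards, sim$standards$target), function(s) {
    fit_standard_curve(s$quantity, s$ct)
  })
  samples <- split(sim$samples, sim$samples$sample)
  out <- lapply(names(samples), function(id) {
    s <- samples[[id]]
    qty <- vapply(c("mt", "nuc"), function(tg) {
      qc <- triplicate_qc(s$ct[s$target == tg], ...)
      if (qc$rejected) return(NA_real_)
      interpolate_quantity(curves[[tg]], qc$mean_ct)$quantity
    }, numeric(1))
    data.frame(sample = id,
               copies = if (anyNA(qty)) NA_real_ else 2 * qty[["mt"]] / qty[["nuc"]],
               rejected = anyNA(qty), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a linear marker series with known slope
#'
#' @param x predictor grid (population doublings or days).
#' @param intercept,slope true linear parameters.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed master seed.
#' @param label stream label.
#' @return list with `data` (x, value) and `truth`.
#' @export
simulate_marker_series <- function(x, intercept, slope, noise_sd = 0,
                                   seed = 1, label = "marker") {
  set.seed(stream_seed(seed, paste0("marker:", label)))
  value <- intercept + slope * x
  if (noise_sd > 0) value <- value + stats::rnorm(length(x), 0, noise_sd)
  list(data = data.frame(x = x, value = value),
       truth = list(intercept = intercept, slope = slope,
                    noise_sd = noise_sd, seed = seed))
}

#' Simulate cohort summary tables with a known standardized effect
#'
#' Control means are fixed; patient means are offset by `true_g` pooled
#' SDs. Observed group means are drawn from the sampling distribution of a
#' mean, observed SDs from the sampling distribution of a sample SD.
#'
#' @param n_cohorts cohorts to generate.
#' @param ctrl_mean,sd true control mean and common within-group SD.
#' @param true_g true standardized effect (patient - control).
#' @param n_per_group participants per group in each cohort.
#' @param outcome,unit labels.
#' @param seed master seed.
#' @return list with `cohorts` (a [cohort_effects()]-ready data.frame) and
#'   `truth` (including the implied true percent difference).
#' @export
simulate_cohorts <- function(n_cohorts = 6, ctrl_mean = 100, sd = 15,
                             true_g = 1.0, n_per_group = 50,
                             outcome = "resting_vo2", unit = "mL/min/kg",
                             seed = 1) {
  set.seed(stream_seed(seed, "cohorts"))
  pat_mean <- ctrl_mean + true_g * sd
  draw_sd <- function() {
    sd * sqrt(stats::rchisq(1, n_per_group - 1) / (n_per_group - 1))
  }
  rows <- lapply(seq_len(n_cohorts), function(i) {
    data.frame(
      cohort = sprintf("cohort%02d", i), outcome = outcome, unit = unit,
      mean_pat = stats::rnorm(1, pat_mean, sd / sqrt(n_per_group)),
      sd_pat = draw_sd(), n_pat = n_per_group,
      mean_ctl = stats::rnorm(1, ctrl_mean, sd / sqrt(n_per_group)),
      sd_ctl = draw_sd(), n_ctl = n_per_group,
      stringsAsFactors = FALSE
    )
  })
  list(cohorts = do.call(rbind, rows),
       truth = list(g = true_g,
                    percent_diff = 100 * (pat_mean - ctrl_mean) / ctrl_mean,
                    ctrl_mean = ctrl_mean, sd = sd,
                    n_per_group = n_per_group, seed = seed))
}

#' Simulate a longitudinal marker for mixed-model calibration
#'
#' `value = baseline + group_effect * [treat] + day_slope * day +
#' donor intercept + residual`, with Gaussian donor intercepts and
#' residuals.
#'
#' @param n_donors_per_group donors per group.
#' @param n_timepoints timepoints per donor.
#' @param group_effect true fixed group effect (0 = null).
#' @param day_slope common time trend.
#' @param donor_sd SD of donor random intercepts.
#' @param resid_sd residual SD.
#' @param baseline intercept.
#' @param days timepoint grid (defaults to `n_timepoints` passages 15 days
#'   apart starting at day 20).
#' @param seed master seed.
#' @param label stream label.
#' @return list with `data` (donor, group, day, value) and `truth`.
#' @export
simulate_longitudinal <- function(n_donors_per_group = 12, n_timepoints = 6,
                                  group_effect = 0, day_slope = 0.02,
                                  donor_sd = 1, resid_sd = 1, baseline = 10,
                                  days = NULL, seed = 1,
                                  label = "longitudinal") {
  set.seed(stream_seed(seed, paste0("long:", label)))
  if (is.null(days)) days <- 20 + 15 * (seq_len(n_timepoints) - 1)
  groups <- c("ctrl", "treat")
  rows <- list()
  for (g in groups) {
    for (i in seq_len(n_donors_per_group)) {
      donor <- sprintf("%s_d%02d", g, i)
      b <- stats::rnorm(1, 0, donor_sd)
      value <- baseline + (g == "treat") * group_effect + day_slope * days +
        b + stats::rnorm(length(days), 0, resid_sd)
      rows[[length(rows) + 1]] <- data.frame(
        donor = donor, group = g, day = days, value = value,
        stringsAsFactors = FALSE
      )
    }
  }
  list(data = do.call(rbind, rows),
       truth = list(group_effect = group_effect, day_slope = day_slope,
                    donor_sd = donor_sd, resid_sd = resid_sd, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
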