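#' Injection scheme for a MitoStress-style assay
#'
#' Fixed four-phase protocol: basal measurements, then sequential injection
#' of oligomycin (ATP synthase inhibitor), FCCP (uncoupler), and
#' rotenone/antimycin A (complex I/III inhibitors). Each phase contributes a
#' declared number of measurement cycles.
#'
#' @param n_basal,n_oligo,n_fccp,n_rotaa measurement cycles per phase
#'   (positive integers).
#' @return An object of class `injection_scheme`.
#' @export
injection_scheme <- function(n_basal = 3, n_oligo = 3, n_fccp = 3,
                             n_rotaa = 3) {
  n <- c(basal = n_basal, oligomycin = n_oligo, fccp = n_fccp,
         rot_aa = n_rotaa)
  if (any(n < 1) || any(n != round(n))) {
    stop("each phase needs a positive integer number of measurements")
  }
  structure(list(phases = names(n), n_per_phase = n,
                 n_total = sum(n)),
            class = "injection_scheme")
}

#' Per-phase membership of an injection scheme
#' @keywords internal
scheme_phase_index <- function(scheme) {
  rep(scheme$phases, times = scheme$n_per_phase)
}

#' One assay well's OCR/ECAR time series
#'
#' @param well well id.
#' @param time_min measurement times (minutes), strictly increasing.
#' @param ocr oxygen consumption rate, pmol O2/min.
#' @param ecar extracellular acidification rate, mpH/min.
#' @param cell_count post-run nuclear count for the well (> 0).
#' @param group,donor optional labels.
#' @return An object of class `well_trace`.
#' @export
well_trace <- function(well, time_min, ocr, ecar, cell_count,
                       group = NA_character_, donor = NA_character_) {
  if (length(time_min) != length(ocr) || length(ocr) != length(ecar)) {
    stop("time_min, ocr and ecar must have equal length")
  }
  if (any(diff(time_min) <= 0)) stop("time_min must be strictly increasing")
  if (any(!is.finite(ocr)) || any(!is.finite(ecar))) {
    stop("OCR/ECAR values must be finite")
  }
  if (!is.finite(cell_count) || cell_count <= 0) {
    stop("cell_count must be > 0")
  }
  structure(list(well = well, group = group, donor = donor,
                 time_min = time_min, ocr = ocr, ecar = ecar,
                 cell_count = cell_count),
            class = "well_trace")
}

#' Summarize a well trace into one representative value pair per phase
#'
#' Defaults: last basal measurement (cells fully equilibrated), minimum OCR
#' under oligomycin (maximal ATP-synthase inhibition), maximum OCR under
#' FCCP (peak uncoupled respiration), minimum OCR after rotenone/antimycin A
#' (non-mitochondrial floor). ECAR is summarized as the mean of the basal
#' phase. The per-phase statistics are configurable.
#'
#' @param trace a [well_trace()].
#' @param scheme an [injection_scheme()]; the trace length must match the
#'   scheme's declared total.
#' @param ocr_stats named list of summary functions per phase.
#' @param ecar_stat summary function for basal-phase ECAR.
#' @return An object of class `phase_summary`: per-phase OCR plus basal ECAR.
#' @export
summarize_phases <- function(trace, scheme,
                             ocr_stats = list(basal = function(x) x[length(x)],
                                              oligomycin = min,
                                              fccp = max,
                                              rot_aa = min),
                             ecar_stat = mean) {
  stopifnot(inherits(trace, "well_trace"), inherits(scheme, "injection_scheme"))
  if (length(trace$ocr) != scheme$n_total) {
    stop(sprintf("trace has %d measurements but scheme declares %d",
                 length(trace$ocr), scheme$n_total))
  }
  phase <- scheme_phase_index(scheme)
  ocr <- vapply(scheme$phases, function(p) {
    x <- trace$ocr[phase == p]
    if (length(x) == 0) stop(sprintf("phase '%s' has no measurements", p))
    ocr_stats[[p]](x)
  }, numeric(1))
  ecar_basal <- ecar_stat(trace$ecar[phase == "basal"])
  structure(list(ocr = ocr, ecar_basal = ecar_basal, well = trace$well),
            class = "phase_summary")
}

#' Derive respiratory parameters from phase summaries
#'
#' Partitions basal respiration into its functional components:
#' non-mitochondrial respiration (rotenone/antimycin A floor), basal
#' mitochondrial respiration, ATP-synthesis-linked respiration (oligomycin
#' sensitive), proton leak (oligomycin insensitive), maximal (FCCP) and
#' spare respiratory capacity, coupling efficiency and the respiratory
#' control ratio. Negative derived rates are never clamped: they raise QC
#' flags so exclusions remain auditable. A well whose basal mitochondrial
#' respiration is not positive is flagged `nonrespiring`, and downstream ATP
#' fluxes are withheld for it.
#'
#' @param phases a `phase_summary`.
#' @return An object of class `resp_profile` with fields `nonmito`,
#'   `basal_mito`, `atp_linked`, `proton_leak`, `maximal`, `spare`,
#'   `coupling_efficiency`, `rcr`, `qc_flags`, `flagged`.
#' @export
derive_respiration <- function(phases) {
  stopifnot(inherits(phases, "phase_summary"))
  o <- phases$ocr
  nonmito <- o[["rot_aa"]]
  basal_mito <- o[["basal"]] - nonmito
  atp_linked <- o[["basal"]] - o[["oligomycin"]]
  proton_leak <- o[["oligomycin"]] - nonmito
  maximal <- o[["fccp"]] - nonmito
  spare <- maximal - basal_mito

  flags <- character(0)
  if (basal_mito <= 0) flags <- c(flags, "nonrespiring")
  if (atp_linked < 0) flags <- c(flags, "negative_atp_linked")
  if (proton_leak < 0) flags <- c(flags, "negative_proton_leak")
  if (maximal < 0) flags <- c(flags, "negative_maximal")
  if (spare < 0) flags <- c(flags, "negative_spare")

  coupling <- if (basal_mito > 0) atp_linked / basal_mito else NA_real_
  rcr <- if (proton_leak > 0) maximal / proton_leak else NA_real_

  structure(list(nonmito = nonmito, basal_mito = basal_mito,
                 atp_linked = atp_linked, proton_leak = proton_leak,
                 maximal = maximal, spare = spare,
                 coupling_efficiency = coupling, rcr = rcr,
                 qc_flags = flags, flagged = length(flags) > 0,
                 well = phases$well),
            class = "resp_profile")
}

#' Glycolytic proton efflux rate
#'
#' Converts basal ECAR to a total proton production rate via the medium
#' buffering power, subtracts the respiratory (CO2-hydration) component, and
#' returns the glycolytic remainder (lactate export). A negative remainder
#' (respiratory acidification exceeding the total) flags the well rather
#' than being clamped.
#'
#' @param phases a `phase_summary`.
#' @param resp a `resp_profile` for the same well.
#' @param k a [stoichiometry_constants()] object.
#' @return list with `ppr_total`, `ppr_resp`, `ppr_glyc` (pmol H+/min) and
#'   `qc_flags`.
#' @export
glycolytic_proton_efflux <- function(phases, resp, k) {
  stopifnot(inherits(k, "stoichiometry_constants"))
  if (k$buffering_power <= 0) stop("buffering_power must be > 0")
  ppr_total <- phases$ecar_basal / k$buffering_power
  ppr_resp <- k$h_resp * resp$basal_mito
  ppr_glyc <- ppr_total - ppr_resp
  flags <- if (ppr_glyc < 0) "negative_ppr_glyc" else character(0)
  list(ppr_total = ppr_total, ppr_resp = ppr_resp, ppr_glyc = ppr_glyc,
       qc_flags = flags)
}

#' ATP production rates from respiration and glycolytic proton efflux
#'
#' OxPhos-derived ATP flux uses only the ATP-synthesis-linked portion of
#' respiration (proton leak and non-mitochondrial oxygen consumption are
#' excluded by construction), converted at 2 x P/O ATP per O2. Glycolytic
#' ATP flux is the lactate-linked proton efflux times the ATP yield per
#' lactate, plus the substrate-level glycolytic ATP linked to mitochondrial
#' glucose oxidation. Totals and the OxPhos fraction follow.
#'
#' @param resp a `resp_profile`.
#' @param ppr_glyc glycolytic proton production rate, pmol H+/min.
#' @param k a [stoichiometry_constants()] object.
#' @return An object of class `atp_flux` with `j_ox`, `j_glyc`, `j_total`
#'   (pmol ATP/min/well) and `ox_fraction`, or a null flux (all `NA`) with a
#'   reason when the well is flagged nonrespiring.
#' @export
atp_fluxes <- function(resp, ppr_glyc, k) {
  stopifnot(inherits(resp, "resp_profile"),
            inherits(k, "stoichiometry_constants"))
  if ("nonrespiring" %in% resp$qc_flags) {
    return(structure(list(j_ox = NA_real_, j_glyc = NA_real_,
                          j_total = NA_real_, ox_fraction = NA_real_,
                          reason = "nonrespiring"),
                     class = "atp_flux"))
  }
  j_ox <- 2 * k$po_oxphos * resp$atp_linked
  j_glyc <- k$atp_per_lactate * ppr_glyc + k$glyc_ox_adjunct * resp$basal_mito
  j_total <- j_ox + j_glyc
  ox_fraction <- if (j_total > 0) j_ox / j_total else NA_real_
  structure(list(j_ox = j_ox, j_glyc = j_glyc, j_total = j_total,
                 ox_fraction = ox_fraction, reason = NULL),
            class = "atp_flux")
}

#' Normalize a well's ATP flux to cell number, volume, and division rate
#'
#' @param flux an `atp_flux`.
#' @param cell_count cells in the well (> 0).
#' @param cell_volume mean cell volume in um^3 (optional).
#' @param division_rate divisions/day (optional).
#' @return list with `per_cell` (pmol ATP/min/cell), `per_volume`
#'   (pmol ATP/min/um^3, `NA` without a volume), `per_division` (pmol ATP
#'   per division-equivalent, `NA` without a positive rate) plus a flag when
#'   a zero division rate makes per-division normalization undefined.
#' @export
normalize_flux <- function(flux, cell_count, cell_volume = NULL,
                           division_rate = NULL) {
  stopifnot(inherits(flux, "atp_flux"))
  if (!is.finite(cell_count) || cell_count <= 0) stop("cell_count must be > 0")
  per_cell <- flux$j_total / cell_count
  per_volume <- if (!is.null(cell_volume)) per_cell / cell_volume else NA_real_
  flags <- character(0)
  per_division <- NA_real_
  if (!is.null(division_rate)) {
    if (is.finite(division_rate) && division_rate > 0) {
      per_division <- per_cell / division_rate
    } else {
      flags <- c(flags, "zero_division_rate")
    }
  }
  list(per_cell = per_cell, per_volume = per_volume,
       per_division = per_division, qc_flags = flags)
}

#' Run the full per-well conversion chain
#'
#' @param trace a [well_trace()].
#' @param scheme an [injection_scheme()].
#' @param k a [stoichiometry_constants()] object.
#' @param cell_volume,division_rate optional normalization inputs.
#' @return one-row data.frame with phase values, respiratory parameters,
#'   ATP fluxes, per-cell normalization and collected QC flags.
#' @export
process_well <- function(trace, scheme, k, cell_volume = NULL,
                         division_rate = NULL) {
  ph <- summarize_phases(trace, scheme)
  resp <- derive_respiration(ph)
  ppr <- glycolytic_proton_efflux(ph, resp, k)
  flux <- atp_fluxes(resp, ppr$ppr_glyc, k)
  norm <- if (is.na(flux$j_total)) {
    list(per_cell = NA_real_, per_volume = NA_real_,
         per_division = NA_real_, qc_flags = character(0))
  } else {
    normalize_flux(flux, trace$cell_count, cell_volume, division_rate)
  }
  flags <- unique(c(resp$qc_flags, ppr$qc_flags, norm$qc_flags))
  data.frame(
    well = trace$well, group = trace$group, donor = trace$donor,
    ocr_basal = ph$ocr[["basal"]], ocr_oligo = ph$ocr[["oligomycin"]],
    ocr_fccp = ph$ocr[["fccp"]], ocr_rotaa = ph$ocr[["rot_aa"]],
    ecar_basal = ph$ecar_basal,
    nonmito = resp$nonmito, basal_mito = resp$basal_mito,
    atp_linked = resp$atp_linked, proton_leak = resp$proton_leak,
    maximal = resp$maximal, spare = resp$spare,
    coupling_efficiency = resp$coupling_efficiency, rcr = resp$rcr,
    ppr_total = ppr$ppr_total, ppr_glyc = ppr$ppr_glyc,
    j_ox = flux$j_ox, j_glyc = flux$j_glyc, j_total = flux$j_total,
    ox_fraction = flux$ox_fraction,
    cell_count = trace$cell_count,
    j_total_per_cell = norm$per_cell,
    qc_flags = paste(flags, collapse = ";"),
    flagged = length(flags) > 0,
    stringsAsFactors = FALSE
  )
}

#' Process every well of a plate
#'
#' @param traces list of [well_trace()] objects.
#' @param scheme an [injection_scheme()].
#' @param k a [stoichiometry_constants()] object.
#' @return data.frame with one row per well (see [process_well()]).
#' @export
process_plate <- function(traces, scheme, k) {
  do.call(rbind, lapply(traces, process_well, scheme = scheme, k = k))
}

#' Aggregate per-well values into group summaries
#'
#' Flagged wells are excluded from the mean but counted, so QC exclusions
#' stay visible. No automatic outlier-well rejection is applied.
#'
#' @param wells data.frame with per-well values (e.g. from
#'   [process_plate()]) including a logical `flagged` column.
#' @param value name of the column to summarize.
#' @param by name of the grouping column (default `"group"`).
#' @return data.frame with `mean`, `sd`, `n`, `n_excluded` per group; a
#'   group with no unflagged wells gets `NA` mean and a reason.
#' @export
aggregate_group <- function(wells, value = "j_total", by = "group") {
  if (nrow(wells) == 0) stop("no wells to aggregate")
  groups <- split(wells, wells[[by]])
  out <- lapply(names(groups), function(g) {
    w <- groups[[g]]
    ok <- !w$flagged & is.finite(w[[value]])
    x <- w[[value]][ok]
    data.frame(
      group = g,
      mean = if (length(x) > 0) mean(x) else NA_real_,
      sd = if (length(x) > 1) stats::sd(x) else NA_real_,
      n = length(x),
      n_excluded = sum(!ok),
      reason = if (length(x) == 0) "all wells flagged" else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
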