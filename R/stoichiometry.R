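#' Stoichiometric constants for ATP-rate conversion
#'
#' Bundles the constants that convert oxygen consumption (OCR) and
#' extracellular acidification (ECAR) into ATP production rates:
#' the P/O ratio of oxidative phosphorylation, the ATP yield per lactate
#' exported by glycolysis, the proton yield of respiratory CO2 hydration,
#' the buffering power of the assay medium, and the small glycolytic
#' substrate-level ATP yield attributable to oxidized glucose.
#'
#' `h_resp` (protons released into the medium per O2 of mitochondrial
#' respiration) is computed from the assay pH and the first pK of CO2
#' hydration unless supplied explicitly:
#' `h_resp = co2_per_o2 / (1 + 10^(pk1 - ph))`.
#'
#' @param po_oxphos ATP synthesized per oxygen atom reduced by
#'   ATP-synthesis-linked respiration (P/O ratio, dimensionless).
#' @param atp_per_lactate ATP per lactate exported (glycolysis).
#' @param buffering_power mpH per pmol H+ in the assay microchamber; must be
#'   positive. Converts ECAR (mpH/min) to a proton production rate
#'   (pmol H+/min).
#' @param glyc_ox_adjunct ATP per O2 of mitochondrial respiration credited to
#'   the glycolytic (substrate-level) steps of glucose oxidation.
#' @param ph assay pH.
#' @param pk1 first pK of CO2 hydration at assay temperature.
#' @param co2_per_o2 CO2 released per O2 consumed (1 for glucose oxidation).
#' @param h_resp protons per O2 of respiration; computed from `ph`/`pk1` when
#'   `NULL`.
#' @param name preset label carried for provenance.
#'
#' @return An object of class `stoichiometry_constants` (a named list).
#' @seealso [stoichiometry_preset()]
#' @export
stoichiometry_constants <- function(po_oxphos,
                                    atp_per_lactate,
                                    buffering_power,
                                    glyc_ox_adjunct,
                                    ph = 7.4,
                                    pk1 = 6.093,
                                    co2_per_o2 = 1.0,
                                    h_resp = NULL,
                                    name = "custom") {
  if (is.null(h_resp)) {
    h_resp <- co2_per_o2 / (1 + 10^(pk1 - ph))
  }
  vals <- c(po_oxphos = po_oxphos, atp_per_lactate = atp_per_lactate,
            buffering_power = buffering_power,
            glyc_ox_adjunct = glyc_ox_adjunct, h_resp = h_resp)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("stoichiometric constants must be finite and nonnegative")
  }
  if (buffering_power <= 0) {
    stop("buffering_power must be > 0")
  }
  structure(
    list(po_oxphos = po_oxphos,
         atp_per_lactate = atp_per_lactate,
         buffering_power = buffering_power,
         glyc_ox_adjunct = glyc_ox_adjunct,
         h_resp = h_resp,
         ph = ph,
         pk1 = pk1,
         co2_per_o2 = co2_per_o2,
         name = name),
    class = "stoichiometry_constants"
  )
}

#' Named stoichiometry presets
#'
#' `"glucose_mookerjee"` carries the glucose-oxidation constants of
#' Mookerjee, Gerencser, Nicholls & Brand (2017, J Biol Chem 292:7189-7207):
#' P/O(oxphos) = 2.486 ATP per O atom, 1 ATP per lactate, 0.167 ATP per O
#' atom (0.333 per O2) of glycolytic substrate-level phosphorylation linked
#' to glucose oxidation, and CO2-derived acidification of 1 CO2 per O2 at
#' pH 7.4 with pK1 = 6.093. The buffering-power default (0.1566 mpH/pmol H+)
#' corresponds to a nominal extracellular-flux assay medium buffer factor of
#' 2.8 mmol/L/pH in a 2.28 uL measurement microchamber. All conversions
#' assume energy sourced entirely from glucose.
#'
#' @param name preset name; currently `"glucose_mookerjee"`.
#' @return A [stoichiometry_constants()] object.
#' @export
stoichiometry_preset <- function(name = "glucose_mookerjee") {
  name <- match.arg(name)
  switch(name,
    glucose_mookerjee = stoichiometry_constants(
      po_oxphos       = 2.486,
      atp_per_lactate = 1.0,
      buffering_power = 1 / (2.8e-3 * 1e-3 * 2.28e-6 * 1e12),
      glyc_ox_adjunct = 2 * 0.167,
      ph              = 7.4,
      pk1             = 6.093,
      co2_per_o2      = 1.0,
      name            = name
    )
  )
}

#' @export
print.stoichiometry_constants <- function(x, ...) {
  cat("Stoichiometric constants (preset: ", x$name, ")\n", sep = "")
  cat(sprintf("  P/O oxphos:        %.3f ATP/O\n", x$po_oxphos))
  cat(sprintf("  ATP per lactate:   %.3f\n", x$atp_per_lactate))
  cat(sprintf("  glyc ox adjunct:   %.3f ATP/O2\n", x$glyc_ox_adjunct))
  cat(sprintf("  H+/O2 respiration: %.3f (pH %.2f, pK1 %.3f)\n",
              x$h_resp, x$ph, x$pk1))
  cat(sprintf("  buffering power:   %.4f mpH/pmol H+\n", x$buffering_power))
  invisible(x)
}
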