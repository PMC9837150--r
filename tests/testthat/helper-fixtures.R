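# shared fixture builders

# a trace with constant OCR/ECAR inside each phase
make_phase_trace <- function(basal, oligo, fccp, rotaa, ecar = 50,
                             n_per_phase = 3, cell_count = 20000,
                             well = "w1") {
  ocr <- rep(c(basal, oligo, fccp, rotaa), each = n_per_phase)
  well_trace(well = well, time_min = seq_along(ocr) * 6.5, ocr = ocr,
             ecar = rep(ecar, length(ocr)), cell_count = cell_count)
}

# constants used by the spec-style worked arithmetic examples
example_constants <- function() {
  stoichiometry_constants(po_oxphos = 2.5, atp_per_lactate = 1,
                          buffering_power = 0.05, glyc_ox_adjunct = 0,
                          h_resp = 1.0)
}

# passage log with prescribed per-passage doubling counts
records_from_pds <- function(pds, interval = 5, plated = 1e6) {
  data.frame(day = interval * seq_along(pds), cells_plated = plated,
             live_harvested = plated * 2^pds, dead_harvested = 0)
}
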