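test_that("phase summarization applies last/min/max/min and basal-mean ECAR", {
  scheme <- injection_scheme()
  tr <- well_trace("w1", time_min = 1:12 * 6.5,
                   ocr = c(98, 99, 100, 32, 30, 31, 150, 160, 155, 12, 10, 11),
                   ecar = c(40, 50, 60, rep(20, 9)), cell_count = 20000)
  ph <- summarize_phases(tr, scheme)
  expect_equal(unname(ph$ocr), c(100, 30, 160, 10))
  expect_equal(ph$ecar_basal, 50)

  flat <- make_phase_trace(50, 50, 50, 50)
  expect_equal(unname(summarize_phases(flat, scheme)$ocr), rep(50, 4))

  short <- well_trace("w2", time_min = 1:11, ocr = rep(50, 11),
                      ecar = rep(10, 11), cell_count = 100)
  expect_error(summarize_phases(short, scheme), "11 measurements")
})

test_that("respiratory parameters follow the phase arithmetic", {
  ph <- summarize_phases(make_phase_trace(100, 30, 160, 10),
                         injection_scheme())
  r <- derive_respiration(ph)
  expect_equal(r$nonmito, 10)
  expect_equal(r$basal_mito, 90)
  expect_equal(r$atp_linked, 70)
  expect_equal(r$proton_leak, 20)
  expect_equal(r$maximal, 150)
  expect_equal(r$spare, 60)
  expect_equal(r$coupling_efficiency, 70 / 90)
  expect_equal(r$rcr, 7.5)
  expect_false(r$flagged)
})

test_that("degenerate and inverted phase values raise QC flags, not clamps", {
  flat <- derive_respiration(
    summarize_phases(make_phase_trace(50, 50, 50, 50), injection_scheme()))
  expect_true("nonrespiring" %in% flat$qc_flags)
  expect_equal(flat$basal_mito, 0)

  inv <- derive_respiration(
    summarize_phases(make_phase_trace(100, 110, 160, 10),
                     injection_scheme()))
  expect_true("negative_atp_linked" %in% inv$qc_flags)
  expect_equal(inv$atp_linked, -10)  # retained, never clamped
})

test_that("glycolytic proton efflux subtracts respiratory acidification", {
  k <- example_constants()
  ph <- summarize_phases(make_phase_trace(100, 30, 160, 10), injection_scheme())
  r <- derive_respiration(ph)
  p <- glycolytic_proton_efflux(ph, r, k)
  expect_equal(p$ppr_total, 1000)
  expect_equal(p$ppr_resp, 90)
  expect_equal(p$ppr_glyc, 910)
  expect_length(p$qc_flags, 0)

  # respiratory acidification exceeding the total flags the well
  ph0 <- summarize_phases(make_phase_trace(2000, 30, 2100, 10, ecar = 50),
                          injection_scheme())
  r0 <- derive_respiration(ph0)
  p0 <- glycolytic_proton_efflux(ph0, r0, k)
  expect_lt(p0$ppr_glyc, 0)
  expect_true("negative_ppr_glyc" %in% p0$qc_flags)
})

test_that("ATP fluxes combine stoichiometric constants as configured", {
  k <- example_constants()
  ph <- summarize_phases(make_phase_trace(100, 30, 160, 10), injection_scheme())
  r <- derive_respiration(ph)
  fl <- atp_fluxes(r, 910, k)
  expect_equal(fl$j_ox, 350)
  expect_equal(fl$j_glyc, 910)
  expect_equal(fl$j_total, 1260)
  expect_equal(fl$ox_fraction, 350 / 1260)

  # nonrespiring wells yield a null flux with a reason
  flat <- derive_respiration(
    summarize_phases(make_phase_trace(50, 50, 50, 50), injection_scheme()))
  nf <- atp_fluxes(flat, 0, k)
  expect_true(is.na(nf$j_total))
  expect_equal(nf$reason, "nonrespiring")
})

test_that("flux identities hold to machine precision on randomized wells", {
  set.seed(42)
  k <- stoichiometry_preset()
  for (i in 1:50) {
    basal <- runif(1, 50, 300)
    oligo <- runif(1, 5, basal)
    rotaa <- runif(1, 1, oligo)
    fccp <- runif(1, basal, 3 * basal)
    ph <- summarize_phases(
      make_phase_trace(basal, oligo, fccp, rotaa, ecar = runif(1, 10, 120)),
      injection_scheme())
    r <- derive_respiration(ph)
    expect_equal(r$basal_mito, r$atp_linked + r$proton_leak,
                 tolerance = 1e-12)
    p <- glycolytic_proton_efflux(ph, r, k)
    fl <- atp_fluxes(r, p$ppr_glyc, k)
    expect_identical(fl$j_total, fl$j_ox + fl$j_glyc)
    expect_true(r$coupling_efficiency >= 0 && r$coupling_efficiency <= 1)
  }
})

test_that("fluxes are homogeneous of degree 1 in the raw measurements", {
  k <- stoichiometry_preset()
  scheme <- injection_scheme()
  tr1 <- make_phase_trace(100, 30, 160, 10, ecar = 60)
  tr3 <- make_phase_trace(300, 90, 480, 30, ecar = 180)
  f1 <- process_well(tr1, scheme, k)
  f3 <- process_well(tr3, scheme, k)
  expect_equal(f3$j_ox, 3 * f1$j_ox)
  expect_equal(f3$j_glyc, 3 * f1$j_glyc)
  expect_equal(f3$j_total, 3 * f1$j_total)
  expect_equal(f3$ox_fraction, f1$ox_fraction)
})

test_that("normalization to cells, volume and division rate is arithmetic", {
  fl <- structure(list(j_ox = 350, j_glyc = 910, j_total = 1260,
                       ox_fraction = 350 / 1260, reason = NULL),
                  class = "atp_flux")
  n <- normalize_flux(fl, 20000)
  expect_equal(n$per_cell, 0.063)
  expect_true(is.na(n$per_volume))
  expect_equal(n$per_cell * 20000, fl$j_total)

  nv <- normalize_flux(fl, 20000, cell_volume = 3000)
  expect_equal(nv$per_volume, 2.1e-5)

  nd <- normalize_flux(fl, 20000, division_rate = 0.4)
  expect_equal(nd$per_division, 0.063 / 0.4)
  nz <- normalize_flux(fl, 20000, division_rate = 0)
  expect_true(is.na(nz$per_division))
  expect_true("zero_division_rate" %in% nz$qc_flags)
  expect_error(normalize_flux(fl, 0), "cell_count")
})

test_that("group aggregation averages unflagged wells and logs exclusions", {
  wells <- data.frame(group = "a", j_total = c(1, 1.2, 0.8),
                      flagged = FALSE)
  agg <- aggregate_group(wells)
  expect_equal(agg$mean, 1)
  expect_equal(agg$n, 3)

  mixed <- data.frame(group = "a", j_total = c(1, 2, 3),
                      flagged = c(FALSE, TRUE, FALSE))
  agg2 <- aggregate_group(mixed)
  expect_equal(agg2$mean, 2)
  expect_equal(agg2$n, 2)
  expect_equal(agg2$n_excluded, 1)

  allbad <- data.frame(group = "a", j_total = 1:2, flagged = TRUE)
  agg3 <- aggregate_group(allbad)
  expect_true(is.na(agg3$mean))
  expect_equal(agg3$reason, "all wells flagged")
  expect_error(aggregate_group(allbad[0, ]), "no wells")
})

test_that("the glucose preset carries the published stoichiometry", {
  k <- stoichiometry_preset("glucose_mookerjee")
  expect_equal(k$po_oxphos, 2.486)
  expect_equal(k$atp_per_lactate, 1.0)
  expect_equal(k$glyc_ox_adjunct, 0.334)
  # H+/O2 from CO2 hydration at pH 7.4, pK1 6.093
  expect_equal(k$h_resp, 1 / (1 + 10^(6.093 - 7.4)))
  expect_gt(k$buffering_power, 0)
})
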