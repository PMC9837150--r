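test_that("triplicate QC ladder reproduces the worked cases", {
  # hard Ct cutoff first, then the surviving duplicate is averaged
  a <- triplicate_qc(c(20.0, 20.1, 34.0))
  expect_equal(a$mean_ct, 20.05)
  expect_false(a$rejected)
  expect_true("ct_above_33_discarded" %in% a$flags)

  b <- triplicate_qc(c(20.0, 20.0, 20.0))
  expect_equal(b$mean_ct, 20)
  expect_length(b$flags, 0)

  c3 <- triplicate_qc(c(10.0, 20.0, 30.0))
  expect_true(c3$rejected)
  expect_true("cv_reject" %in% c3$flags)
  expect_true(is.na(c3$mean_ct))
})

test_that("QC never averages a flagged value and flags accumulate", {
  res <- triplicate_qc(c(20.0, 20.1, 34.0))
  expect_false(34.0 %in% res$ct_used)

  # an isolated late outlier is removed and recorded
  out <- triplicate_qc(c(20.0, 20.1, 25.0))
  expect_true("cv_inspected" %in% out$flags)
  expect_true("outlier_removed" %in% out$flags)
  expect_equal(out$mean_ct, 20.05)

  gone <- triplicate_qc(c(34, 35, 36))
  expect_true(gone$rejected)
  expect_match(gone$reason, "hard cutoff")
})

test_that("mtDNA copy number doubles exactly per delta-Ct unit", {
  expect_equal(mtdna_copy_number(20, 28), 512)
  expect_equal(mtdna_copy_number(20, 20), 2)
  for (dct in c(-2, 0, 3.5, 8)) {
    expect_equal(mtdna_copy_number(20, 20 + dct + 1),
                 2 * mtdna_copy_number(20, 20 + dct))
  }
  expect_true(is.na(mtdna_copy_number(NA, 28)))
})

test_that("standard curves fit, report efficiency, and invert", {
  sc <- fit_standard_curve(c(1, 10, 100), c(30, 26.678, 23.356))
  expect_equal(sc$slope, -3.322)
  expect_equal(sc$efficiency, 1.00, tolerance = 1e-4)
  q <- interpolate_quantity(sc, 26.678)
  expect_equal(q$quantity, 10, tolerance = 1e-6)
  expect_false(q$extrapolated)
  expect_true(interpolate_quantity(sc, 35)$extrapolated)

  expect_error(fit_standard_curve(c(1, 10), c(30, 27)), "at least 3")
  expect_error(fit_standard_curve(c(1, 10, 100), c(23, 27, 30)), "negative")
  # fit-then-interpolate is the identity on exactly log-linear standards
  qq <- interpolate_quantity(sc, c(30, 26.678, 23.356))$quantity
  expect_equal(qq, c(1, 10, 100), tolerance = 1e-6)
})

test_that("Dixon's Q removes only extremes beyond the critical value", {
  d <- dixon_q(c(1.00, 1.01, 2.00))
  expect_equal(d$outlier_index, 3)
  expect_gt(d$q, 0.970)

  expect_true(is.na(dixon_q(c(1, 1, 1))$outlier_index))
  expect_true(is.na(dixon_q(c(1.00, 1.02, 1.50))$outlier_index))
  # the same borderline set is rejected at the laxer level
  expect_equal(dixon_q(c(1.00, 1.02, 1.50), alpha = 0.10)$outlier_index, 3)
  expect_error(dixon_q(c(1, 2)), "3-7")
})

test_that("duplicate T/S runs reconcile by the 7% rule", {
  ok <- reconcile_duplicate_runs(1.00, 1.05)
  expect_equal(ok$final, 1.025)
  expect_equal(ok$status, "accepted")

  third <- reconcile_duplicate_runs(1.00, 1.20, run3 = 1.04)
  expect_equal(third$final, 1.02)
  expect_equal(sort(third$runs_used), c(1.00, 1.04))
  expect_equal(third$status, "third_run")

  un <- reconcile_duplicate_runs(1.00, 1.20)
  expect_true(is.na(un$final))
  expect_equal(un$status, "unresolved")
})

test_that("cf-DNA ratio is a guarded quotient", {
  expect_equal(cfdna_ratio(200, 100), 2)
  expect_equal(cfdna_ratio(0, 100), 0)
  expect_error(cfdna_ratio(10, 0), "> 0")
})

test_that("simulated qPCR with realistic noise recovers copy numbers", {
  sim <- simulate_qpcr(true_copies = 400, n_samples = 500,
                       efficiency = 0.95, ct_noise_sd = 0.1, seed = 11)
  rec <- recover_copy_numbers(sim)
  expect_false(any(rec$rejected))
  rel_err <- abs(rec$copies - 400) / 400
  expect_gte(mean(rel_err <= 0.10), 0.95)

  # noise-free, efficiency 1: recovery is exact
  ex <- recover_copy_numbers(simulate_qpcr(true_copies = 512, n_samples = 3,
                                           efficiency = 1, ct_noise_sd = 0,
                                           seed = 1))
  expect_equal(ex$copies, rep(512, 3), tolerance = 1e-9)
})

test_that("injected Ct outliers are removed by the QC ladder", {
  removed <- vapply(1:50, function(s) {
    sim <- simulate_qpcr(true_copies = 400, n_samples = 1,
                         ct_noise_sd = 0.05, outlier_frac = 1,
                         outlier_shift = 5, seed = s)
    mt <- sim$samples$ct[sim$samples$target == "mt"]
    qc <- triplicate_qc(mt)
    !qc$rejected && length(qc$ct_used) == 2 && !(max(mt) %in% qc$ct_used)
  }, logical(1))
  expect_true(all(removed))
})
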