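test_that("population doublings count live plus dead harvested cells", {
  expect_equal(population_doubling(5e5, 2e6, 0, 5),
               list(pd = 2, division_rate = 0.4))
  expect_equal(population_doubling(1e6, 1e6, 0, 5)$pd, 0)
  r <- population_doubling(1e6, 1.2e6, 0.3e6, 6)
  expect_equal(r$pd, log2(1.5))
  expect_equal(r$division_rate, log2(1.5) / 6)
  expect_error(population_doubling(0, 1e6, 0, 5), "cells_plated")
  expect_error(population_doubling(1e6, 0, 0, 5), "harvested")
})

test_that("trajectories accumulate doublings in day order", {
  traj <- build_trajectory(records_from_pds(c(2, 1.5, 1)))
  expect_equal(traj$cumulative_pd, c(2, 3.5, 4.5))
  expect_equal(traj$division_rate, c(2, 1.5, 1) / 5)

  empty <- data.frame(day = numeric(0), cells_plated = numeric(0),
                      live_harvested = numeric(0),
                      dead_harvested = numeric(0))
  expect_error(build_trajectory(empty), "no passage")
  one <- build_trajectory(records_from_pds(1.2))
  expect_equal(nrow(one), 1)

  bad <- records_from_pds(c(1, 1)); bad$day <- c(10, 5)
  expect_error(build_trajectory(bad), "strictly increasing")
})

test_that("rate-rule Hayflick limit needs two consecutive slow passages", {
  mk <- function(pds, rates) {
    rec <- records_from_pds(pds)
    traj <- build_trajectory(rec)
    traj$division_rate <- rates  # prescribe rates directly
    traj
  }
  traj <- mk(c(3, 2.5, 1, 0.1, 0.08), c(0.5, 0.3, 0.1, 0.009, 0.008))
  h <- hayflick_limit(traj)
  expect_equal(h$status, "terminated")
  expect_equal(h$hayflick_pd, 6.68)

  cens <- hayflick_limit(mk(c(3, 2.5, 1), c(0.5, 0.3, 0.1)))
  expect_equal(cens$status, "censored")
  expect_equal(cens$hayflick_pd, 6.5)

  # a non-consecutive early dip is ignored
  dip <- mk(c(1, 1, 1, 1), c(0.009, 0.02, 0.009, 0.008))
  expect_equal(hayflick_limit(dip)$hayflick_pd, 4)
})

test_that("window rule terminates on < 1 doubling per 30 days", {
  pds <- c(3, 2.5, 2, 1.5, 0.2, 0.1, 0.05, 0.05)
  traj <- build_trajectory(records_from_pds(pds, interval = 10))
  h <- hayflick_limit(traj, rule = "window")
  # first window [day-30, day] with < 1 PD: day 70 covers pds 0.2+0.1+0.05
  expect_equal(h$status, "terminated")
  expect_equal(h$day, 70)
  expect_equal(h$hayflick_pd, sum(pds[1:7]))
})

test_that("Hayflick limit is monotone in the rate threshold", {
  for (s in 1:20) {
    sim <- simulate_lifespan(r0 = runif(1, 0.3, 0.7),
                             lifespan_days = runif(1, 120, 260),
                             noise_sd = 0.05, seed = s, label = "mono")
    traj <- build_trajectory(sim$records)
    h_low <- hayflick_limit(traj, rate_threshold = 0.01)$hayflick_pd
    h_high <- hayflick_limit(traj, rate_threshold = 0.05)$hayflick_pd
    expect_lte(h_high, h_low)
  }
})

test_that("windowed contrasts use two-stage donor averaging", {
  d <- expand.grid(donor = c("c1", "c2", "t1", "t2"), day = c(30, 60, 90))
  d$group <- ifelse(grepl("^c", d$donor), "ctrl", "treat")
  d$value <- ifelse(d$group == "ctrl", 100, 191)
  wc <- window_contrast(d, treat = "treat", ctrl = "ctrl", window = c(20, 150))
  expect_equal(wc$percent_diff, 91)

  d$value <- 100
  wc0 <- window_contrast(d, "treat", "ctrl", c(20, 150))
  expect_equal(wc0$percent_diff, 0)
  expect_equal(wc0$hedges_g, 0)

  # a donor sampled much more densely must not dominate the group mean
  d2 <- rbind(
    data.frame(donor = "t1", group = "treat", day = c(30, 60), value = 10),
    data.frame(donor = "t2", group = "treat", day = seq(25, 145, 10),
               value = 30),
    data.frame(donor = c("c1", "c2"), group = "ctrl", day = 50, value = 10)
  )
  expect_equal(window_contrast(d2, "treat", "ctrl", c(20, 150))$mean_treat,
               20)

  expect_error(window_contrast(d, "treat", "ctrl", c(500, 600)),
               "no observations")
})

test_that("window contrasts recover an injected offset from noisy data", {
  errs <- vapply(1:40, function(s) {
    mk <- function(g, mu) {
      do.call(rbind, lapply(1:3, function(i) {
        sim <- simulate_marker_series(seq(20, 150, 15), intercept = mu,
                                      slope = 0, noise_sd = 0.1 * mu,
                                      seed = s, label = paste0(g, i))
        data.frame(donor = paste0(g, i), group = g, day = sim$data$x,
                   value = sim$data$value)
      }))
    }
    d <- rbind(mk("ctrl", 100), mk("treat", 150))
    window_contrast(d, "treat", "ctrl", c(20, 150))$percent_diff - 50
  }, numeric(1))
  expect_lt(abs(mean(errs)), 5)
})

test_that("mixed-model test rejects invalid designs and finds real effects", {
  sim <- simulate_longitudinal(n_donors_per_group = 6, n_timepoints = 5,
                               group_effect = 10, donor_sd = 0.5,
                               resid_sd = 0.5, seed = 7)
  res <- lmm_group_test(sim$data)
  expect_lt(res$p, 1e-4)
  expect_equal(res$estimate, 10, tolerance = 0.2)

  single <- sim$data[sim$data$donor %in% c("ctrl_d01", "treat_d01"), ]
  expect_error(lmm_group_test(single), "at least 2 donors")
  short <- sim$data[sim$data$day <= 35, ]
  expect_error(lmm_group_test(short), "3 timepoints")
})

test_that("marker batches are BH-adjusted preserving p-value order", {
  sims <- lapply(1:4, function(i) {
    eff <- c(0, 0, 5, 10)[i]
    s <- simulate_longitudinal(n_donors_per_group = 4, n_timepoints = 4,
                               group_effect = eff, seed = 20 + i,
                               label = paste0("m", i))
    cbind(marker = paste0("m", i), s$data)
  })
  batch <- lmm_marker_batch(do.call(rbind, sims))
  expect_equal(nrow(batch), 4)
  ord_p <- order(batch$p)
  expect_equal(order(batch$q), ord_p)
  expect_true(all(batch$q >= batch$p))
  expect_true(all(batch$q <= 1))
})

test_that("polynomial fits are exact on cubics and guard their order", {
  x <- seq(0, 10, length.out = 9)
  y <- 1 + 2 * x - 0.5 * x^2 + 0.1 * x^3
  fit <- fit_trajectory_polynomial(x, y, order = 3)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  expect_equal(fit$coefficients, c(1, 2, -0.5, 0.1), tolerance = 1e-6)

  expect_error(fit_trajectory_polynomial(x[1:6], y[1:6], order = 5),
               "more than 6 points")
  # automatic selection keeps the cubic for cubic data
  auto <- fit_trajectory_polynomial(x, y)
  expect_equal(auto$order, 3)
  # and picks order 5 when the data demand it
  y5 <- x^5 - 3 * x^4 + x
  x5 <- seq(0, 4, length.out = 12)
  auto5 <- fit_trajectory_polynomial(x5, x5^5 - 3 * x5^4 + x5)
  expect_equal(auto5$order, 5)
})

test_that("slope_rate is exact on collinear points and shift-invariant", {
  ts <- slope_rate(c(0, 10, 20), c(1.20, 1.10, 1.00))
  expect_equal(ts$slope, -0.010)
  dnam <- slope_rate(c(25, 50, 75), c(30, 35, 40))
  expect_equal(dnam$slope, 0.2)
  shifted <- slope_rate(c(0, 10, 20), c(1.20, 1.10, 1.00) + 5)
  expect_equal(shifted$slope, ts$slope)
  expect_error(slope_rate(1, 1), "at least 2")

  expect_equal(rate_ratio(-0.0262, -0.010), 162)
  expect_error(rate_ratio(1, 0), "zero control slope")
})

test_that("per-cell normalization handles undetectables per policy", {
  expect_equal(per_cell_normalize(600, 3e5), 2e-3)
  expect_equal(per_cell_normalize(0, 1e5), 0)
  expect_true(is.na(per_cell_normalize(NA_real_, 1e5)))
  expect_equal(per_cell_normalize(NA_real_, 1e5, undetectable = "zero"), 0)
  expect_error(per_cell_normalize(10, 0), "cell_count")
})
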