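test_that("normalize_to_control cancels shared bleaching exactly", {
  truth <- mtq2_optones()
  # identical trace and control: normalisation gives the constant 1
  spec <- generator_spec(truth, noise_sd = 0, n_replicates = 1, seed = 1,
                         bleach_per_reading = 0.01)
  tr <- gen_cycle_traces(spec)
  self <- cycle_trace_set(tr$control_readings, tr$dark_times_s,
                          tr$dose_per_flash, tr$flash_rate_hz,
                          control_readings = tr$control_readings)
  ns <- normalize_to_control(self)
  expect_equal(ns$readings$intensity_au,
               rep(1, nrow(ns$readings)), tolerance = 1e-12)

  # shared 1%-per-reading bleach cancels: normalised trace equals the
  # noise-free model trace rescaled to its first point
  nt <- normalize_to_control(tr)
  spec0 <- generator_spec(truth, noise_sd = 0, n_replicates = 1, seed = 1)
  nt0 <- normalize_to_control(gen_cycle_traces(spec0))
  expect_equal(nt$readings$intensity_au, nt0$readings$intensity_au,
               tolerance = 1e-10)

  bare <- cycle_trace_set(tr$readings, tr$dark_times_s, tr$dose_per_flash,
                          tr$flash_rate_hz)
  expect_error(normalize_to_control(bare), "missing control")
  short <- tr$control_readings[tr$control_readings$cycle_index > 1, ]
  mism <- cycle_trace_set(tr$readings, tr$dark_times_s, tr$dose_per_flash,
                          tr$flash_rate_hz, control_readings = short)
  expect_error(normalize_to_control(mism), "protocol mismatch")
})

test_that("two-stage pipeline: exact at zero noise, close under noise", {
  truth <- mtq2_optones()
  nt <- clean_normalized_traces(truth)
  ce <- fit_cycle_exponentials(nt)
  expect_true(ce$converged)
  k <- forward_rate(56, truth)
  tau_true <- 4 / k$k_app            # flashes
  expect_equal(unname(coef(ce)["tau_flashes"]), tau_true,
               tolerance = 1e-6)
  # recovered amplitudes against dark time give back A0 and r
  amps <- data.frame(dark_time_s = nt$dark_times_s,
                     A = unname(coef(ce)[-(1:2)]))
  dr <- fit_dark_relaxation(amps)
  expect_equal(unname(coef(dr)["r"]), 6.8, tolerance = 1e-6)

  # seeded noisy data at the plate protocol: within 5%
  spec <- generator_spec(truth, noise_sd = 0.003, seed = 1)
  ntn <- normalize_to_control(gen_cycle_traces(spec))
  cen <- fit_cycle_exponentials(ntn)
  expect_rel_equal(coef(cen)["tau_flashes"], tau_true, 0.05)
  expect_rel_equal(coef(cen)[-(1:2)], coef(ce)[-(1:2)], 0.25)

  expect_error(fit_cycle_exponentials(
    cycle_trace_set(nt$readings, nt$dark_times_s, 14, 4)),
    "normalised")
})

test_that("dark relaxation fit: degenerate input and noisy recovery", {
  t <- c(1, 2, 5, 10, 20, 60, 180)
  expect_error(fit_dark_relaxation(data.frame(dark_time_s = c(1, 1, 2),
                                              A = c(1, 1, 2))),
               "3 distinct")
  flat <- fit_dark_relaxation(data.frame(dark_time_s = t,
                                         A = rep(0.1, 7)))
  expect_false(flat$converged)
  expect_match(flat$flags, "non_identifiable")

  # median error across seeded repeats at 5% amplitude noise stays
  # within 10% of truth
  errs <- vapply(1:40, function(s) {
    A <- dark_recovery_amplitude(0.19, 6.8, t)
    set.seed(s)
    An <- A + stats::rnorm(length(t), 0, 0.05 * 0.19)
    fit <- fit_dark_relaxation(data.frame(dark_time_s = t, A = An))
    abs(coef(fit)["r"] - 6.8) / 6.8
  }, 0)
  expect_lt(stats::median(errs), 0.10)
})

test_that("global switch fit: donor and acceptor recovery", {
  truth <- mtq2_optones()
  g <- fit_global_switch(clean_normalized_traces(truth), "donor")
  expect_true(g$converged)
  th <- coef(g)
  expect_equal(unname(th[c("transfer_limit", "sensitivity", "r")]),
               c(0.189, 162, 6.8), tolerance = 1e-6)
  # derived ED50 equals ed50() at the fitted parameters exactly
  pc <- photocycle_params(th["sensitivity"], th["r"],
                          th["transfer_limit"], "donor")
  expect_identical(g$derived$ed50_umol_m2_per_flash$value, ed50(pc, 4))

  # noisy donor: all parameters within 10% of truth (3 replicates
  # averaged per the plate workflow)
  spec <- generator_spec(truth, noise_sd = 0.005, seed = 42)
  gn <- fit_global_switch(normalize_to_control(gen_cycle_traces(spec)),
                          "donor")
  expect_rel_equal(coef(gn)["transfer_limit"], 0.189, 0.10)
  expect_rel_equal(coef(gn)["sensitivity"], 162, 0.10)
  expect_rel_equal(coef(gn)["r"], 6.8, 0.10)

  # acceptor mirror at the tenfold higher dose
  atruth <- ypet_optones()
  aspec <- generator_spec(atruth, noise_sd = 0.005, seed = 42,
                          protocol = list(dose_per_flash = 140))
  an <- fit_global_switch(normalize_to_control(gen_cycle_traces(aspec)),
                          "acceptor")
  expect_rel_equal(coef(an)["transfer_limit"], 0.535, 0.10)
  expect_rel_equal(coef(an)["sensitivity"], 559, 0.10)
  expect_rel_equal(coef(an)["r"], 8.0, 0.10)
})

test_that("reversible dose-series fit recovers the generating model", {
  doses <- c(14, 42, 140, 420)
  x <- 0:49
  mk <- function(sens, r, lim, plateau = 1, rate = 4) do.call(
    rbind, lapply(doses, function(d) {
      kf <- d / sens; kr <- 1 / (r * rate); kapp <- kf + kr
      m <- lim * kf / kapp
      data.frame(dose_per_flash_umol_m2 = d, reading_index = x,
                 intensity_au = plateau * (1 - lim + m * (1 - exp(-kapp * x))))
    }))
  clean <- mk(200, 5, 0.2)
  fit <- fit_reversible_dose_series(clean, "donor")
  expect_equal(unname(coef(fit)[c("transfer_limit", "sensitivity", "r")]),
               c(0.2, 200, 5), tolerance = 1e-6)
  expect_equal(fit$derived$ed50_umol_m2_per_flash$value, 200 / (4 * 5))

  # drop_first honoured: perturbing the first reading of each curve has
  # no effect once dropped
  spiked <- clean
  spiked$intensity_au[spiked$reading_index == 0] <- 99
  fit2 <- fit_reversible_dose_series(spiked, "donor", drop_first = TRUE)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-6)

  # noisy recovery within 10% (sens ~200 umol m^-2, r ~5 s)
  set.seed(7)
  noisy <- clean
  noisy$intensity_au <- noisy$intensity_au + rnorm(nrow(noisy), 0, 0.005)
  fitn <- fit_reversible_dose_series(noisy, "donor")
  expect_rel_equal(coef(fitn)["sensitivity"], 200, 0.10)
  expect_rel_equal(coef(fitn)["r"], 5, 0.10)

  expect_error(fit_reversible_dose_series(
    clean[clean$dose_per_flash_umol_m2 < 100, ], "donor"), "3 doses")
})

test_that("single-site fit: exact recovery, ED50 definition, F test", {
  xs <- c(14, 42, 140, 420)
  y <- 10 / (1 + 100 / xs)
  fit <- fit_single_site(xs, y)
  expect_equal(unname(coef(fit)), c(10, 100), tolerance = 1e-7)
  # response at x = b is half the maximum
  a <- coef(fit)["max"]; b <- coef(fit)["ed50"]
  expect_equal(unname(a / (1 + b / b)), unname(a) / 2)

  # two groups, shared max, distinct ED50: F-test rejects sharing
  set.seed(11)
  x2 <- rep(rep(xs, each = 6), 2)
  g2 <- rep(c("fast", "slow"), each = 24)
  b_true <- c(fast = 48, slow = 140)
  y2 <- 10 / (1 + b_true[g2] / x2) + rnorm(48, 0, 0.25)
  full <- fit_single_site(x2, y2, group = g2)
  restricted <- fit_single_site(x2, y2, group = g2, shared_ed50 = TRUE)
  expect_rel_equal(coef(full)["ed50[fast]"], 48, 0.10)
  expect_rel_equal(coef(full)["ed50[slow]"], 140, 0.10)
  ft <- nested_f_test(restricted, full)
  expect_lt(ft$p, 0.01)

  expect_error(fit_single_site(xs, rep(0, 4)), "degenerate")
})

test_that("two-stage and global relaxation estimates agree under noise", {
  truth <- mtq2_optones()
  spec <- generator_spec(truth, noise_sd = 0.005, seed = 3)
  nt <- normalize_to_control(gen_cycle_traces(spec))
  g <- fit_global_switch(nt, "donor")
  ce <- fit_cycle_exponentials(nt)
  amps <- data.frame(dark_time_s = nt$dark_times_s,
                     A = unname(coef(ce)[-(1:2)]))
  dr <- fit_dark_relaxation(amps)
  r_global <- coef(g)["r"]; se_g <- g$params["r", "se"]
  r_stage <- coef(dr)["r"]; se_s <- dr$params["r", "se"]
  expect_lt(abs(r_global - r_stage),
            1.96 * sqrt(se_g^2 + se_s^2) + 1e-12)
})
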