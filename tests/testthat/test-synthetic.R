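test_that("generators are deterministic in the seed", {
  truth <- mtq2_optones()
  s1 <- generator_spec(truth, noise_sd = 0.004, seed = 9)
  expect_identical(gen_cycle_traces(s1), gen_cycle_traces(s1))
  s2 <- generator_spec(truth, noise_sd = 0.004, seed = 10)
  expect_false(identical(gen_cycle_traces(s1)$readings$intensity_au,
                         gen_cycle_traces(s2)$readings$intensity_au))
  rt <- generator_spec(list(L = 1, S = 0.5, tau_lit = 300,
                            tau_dark = 600), noise_sd = 0.01, seed = 3)
  expect_identical(gen_reporter_series(rt), gen_reporter_series(rt))
  tt <- generator_spec(list(Max = 0.1, ED50 = 48), noise_sd = 0.02,
                       seed = 3)
  expect_identical(gen_translocation_ratios(tt),
                   gen_translocation_ratios(tt))
  pt <- generator_spec(truth, noise_sd = 0.003, seed = 3)
  expect_identical(gen_dark_recovery_plate(pt),
                   gen_dark_recovery_plate(pt))
  # generators do not disturb the session RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_cycle_traces(s1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noise-free cycle traces equal the closed-form model", {
  truth <- mtq2_optones()
  spec <- generator_spec(truth, noise_sd = 0, n_replicates = 1, seed = 1)
  tr <- gen_cycle_traces(spec)
  m <- trace_model_params(truth, offset = 1, flash_rate_hz = 4,
                          dose_per_flash = 14)
  rd <- tr$readings
  expected <- dequench_trace(m, rd$reading_index,
                             tr$dark_times_s[rd$cycle_index])
  expect_equal(rd$intensity_au, expected, tolerance = 1e-12)
  # normalisation of clean, bleach-free data only rescales by the first
  # point
  nt <- normalize_to_control(tr)
  expect_equal(nt$readings$intensity_au, expected / expected[1],
               tolerance = 1e-12)
})

test_that("bleach-cancellation: residual trend after control correction", {
  truth <- mtq2_optones()
  spec <- generator_spec(truth, noise_sd = 0.003,
                         bleach_per_reading = 0.002, seed = 21)
  nt <- normalize_to_control(gen_cycle_traces(spec))
  spec0 <- generator_spec(truth, noise_sd = 0, n_replicates = 1, seed = 1)
  nt0 <- normalize_to_control(gen_cycle_traces(spec0))
  avg <- lovfret:::.average_replicates(nt$readings)
  m <- merge(avg, nt0$readings[, c("cycle_index", "reading_index",
                                   "intensity_au")],
             by = c("cycle_index", "reading_index"))
  m <- m[order(m$cycle_index, m$reading_index), ]
  resid <- m$intensity_au.x - m$intensity_au.y
  # systematic residual trend below 0.05% per reading
  slope <- stats::coef(stats::lm(resid ~ seq_along(resid)))[2]
  expect_lt(abs(slope), 5e-4)
})

test_that("plate recovery traces support relaxation-rate discrimination", {
  p <- mtq2_optones()
  spec <- generator_spec(p, noise_sd = 0.002, n_replicates = 8, seed = 2,
                         protocol = list(n_cycles = 20, cycle_s = 3))
  d <- gen_dark_recovery_plate(spec)
  expect_equal(nrow(d), 8 * 20)
  expect_equal(max(d$time_s), 57)
  fit_r <- function(dd) {
    avg <- stats::aggregate(intensity_au ~ time_s, dd, mean)
    fit <- fit_dark_relaxation(data.frame(dark_time_s = avg$time_s,
                                          A = avg$intensity_au),
                               baseline = "fit")
    unname(coef(fit)["r"])
  }
  expect_rel_equal(fit_r(d), 6.8, 0.10)
  # ordering of two constructs (r = 6.8 vs 11.5) preserved across seeds
  ok <- sum(vapply(1:40, function(s) {
    fast <- generator_spec(p, noise_sd = 0.002, n_replicates = 3,
                           seed = s)
    slow <- generator_spec(photocycle_params(124, 11.5, 0.236),
                           noise_sd = 0.002, n_replicates = 3,
                           seed = s + 1000)
    fit_r(gen_dark_recovery_plate(fast)) <
      fit_r(gen_dark_recovery_plate(slow))
  }, TRUE))
  expect_gte(ok, 38)   # >= 95%
})

test_that("translocation generator wires rate, dose and baseline", {
  truth <- list(Max = 0.1, ED50 = 48)
  spec <- generator_spec(truth, noise_sd = 0, n_replicates = 1, seed = 1)
  d <- gen_translocation_ratios(spec)
  # per-flash slope at dose = ED50 equals Max / 2 by construction
  one <- d[d$dose_per_flash_umol_m2 == 48 & d$cycle_index == 1, ]
  expect_equal(nrow(one), 0)   # 48 not in default dose ladder
  spec2 <- generator_spec(truth, noise_sd = 0, n_replicates = 1, seed = 1,
                          protocol = list(doses = c(14, 48, 140)))
  d2 <- gen_translocation_ratios(spec2)
  at_ed50 <- d2[d2$dose_per_flash_umol_m2 == 48 & d2$cycle_index == 1, ]
  expect_equal(suppressWarnings(export_rate(at_ed50))$gradient, -0.05,
               tolerance = 1e-10)
  expect_equal(at_ed50$nc_ratio[1], 2.37)
  # zero dose gives a flat series
  spec3 <- generator_spec(truth, noise_sd = 0, n_replicates = 1, seed = 1,
                          protocol = list(doses = c(1e-9, 14, 140)))
  d3 <- gen_translocation_ratios(spec3)
  flat <- d3[d3$dose_per_flash_umol_m2 == 1e-9 & d3$cycle_index == 1, ]
  expect_lt(abs(suppressWarnings(export_rate(flat))$gradient), 1e-10)
})

test_that("end-to-end translocation pipeline recovers ED50", {
  truth <- list(Max = 0.1, ED50 = 48)
  spec <- generator_spec(truth, noise_sd = 0.02, n_replicates = 6,
                         seed = 17)
  d <- gen_translocation_ratios(spec)
  grads <- do.call(rbind, lapply(
    split(d, list(d$sample_id, d$dose_per_flash_umol_m2, d$cycle_index)),
    function(dd) data.frame(sample = dd$sample_id[1],
                            dose = dd$dose_per_flash_umol_m2[1],
                            rate = -export_rate(dd)$gradient)))
  per_dose <- stats::aggregate(rate ~ dose + sample, grads, mean)
  fit <- dose_response(per_dose)
  expect_rel_equal(coef(fit)["ed50"], 48, 0.15)
  expect_rel_equal(coef(fit)["max"], 0.1, 0.15)
})

test_that("trace CSV and parameter JSON round trips", {
  truth <- ypet_optones()
  spec <- generator_spec(truth, noise_sd = 0.002, n_replicates = 2,
                         seed = 4, protocol = list(dose_per_flash = 140))
  tr <- gen_cycle_traces(spec)
  path <- tempfile(fileext = ".csv")
  write_trace_csv(tr, path, construct = "ypet-optones")
  back <- read_trace_csv(path)
  expect_equal(back$dark_times_s, tr$dark_times_s)
  expect_equal(back$dose_per_flash, 140)
  expect_equal(back$readings$intensity_au, tr$readings$intensity_au,
               tolerance = 1e-12)
  expect_equal(back$control_readings$intensity_au,
               tr$control_readings$intensity_au, tolerance = 1e-12)
  unlink(path)

  js <- params_to_json(truth)
  p2 <- params_from_json(js)
  expect_identical(p2, truth)

  g <- fit_global_switch(normalize_to_control(tr), "acceptor")
  report <- jsonlite::fromJSON(fit_to_json(g))
  expect_equal(report$params$sensitivity$best_fit,
               unname(coef(g)["sensitivity"]))
  expect_equal(report$model, "global_switch")
})
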