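# Seeded generators producing every input the pipeline consumes, with the
# statistical structure the analysis assumes: noise-free model traces from
# the closed-form equations, multiplied by a per-reading photobleaching
# factor shared with a matched LOV2-free control, plus independent
# homoscedastic Gaussian noise on every reading.
#
# Defaults are the plate protocol: cycles of 20 flashes of 14 umol m^-2
# at 4 Hz, a 600 s sentinel first dark period, then 12 log-spaced dark
# periods between 1 and 180 s, 3 replicate repeats, noise sd 0.3-0.5% of
# the normalised signal.

# evaluate thunk with a private RNG stream so generators are pure
# functions of their seed
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Default dark-time schedule of the cycling protocol
#'
#' The 600 s sentinel (first dark period of a session, effectively
#' infinite) followed by `n` log-spaced dark times between `t_min` and
#' `t_max` seconds. The exact schedule of the plate protocol is not
#' enumerated anywhere; a log-spaced ladder is the documented assumption.
#'
#' @param n Number of post-sentinel dark periods (default 12).
#' @param t_min,t_max Range of the ladder, s (defaults 1 and 180).
#' @param sentinel_s First-period sentinel, s (default 600).
#' @return Numeric vector of length `n + 1`.
#' @export
default_dark_times <- function(n = 12, t_min = 1, t_max = 180,
                               sentinel_s = 600) {
  c(sentinel_s, exp(seq(log(t_min), log(t_max), length.out = n)))
}

#' Specification for the synthetic-data generators
#'
#' @param truth Ground-truth parameter object: a [photocycle_params()]
#'   for trace generators, a [reporter_kinetics()] for reporter series,
#'   or a list like `list(Max = ..., ED50 = ...)` for dose-response.
#' @param protocol Named list of protocol settings; unset entries take
#'   the generator's documented defaults.
#' @param noise_sd Gaussian noise sd as a fraction of the normalised
#'   signal (default 0.003).
#' @param bleach_per_reading Multiplicative photobleaching per reading,
#'   in [0, 1) (default 0), shared between construct and control.
#' @param n_replicates Number of replicate samples (default 3).
#' @param seed Integer RNG seed; the generators are deterministic in it.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(truth, protocol = list(), noise_sd = 0.003,
                           bleach_per_reading = 0, n_replicates = 3,
                           seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (bleach_per_reading < 0 || bleach_per_reading >= 1)
    stop("bleach_per_reading must lie in [0, 1)")
  structure(list(truth = truth, protocol = protocol, noise_sd = noise_sd,
                 bleach_per_reading = bleach_per_reading,
                 n_replicates = n_replicates, seed = seed),
            class = "generator_spec")
}

.proto <- function(spec, name, default) {
  v <- spec$protocol[[name]]
  if (is.null(v)) default else v
}

#' Generate dequench/requench cycle traces with a matched control
#'
#' Emits the noise-free closed-form trace (donor dequench or acceptor
#' quench, per the truth's mode) for each cycle of the protocol, applies
#' a cumulative multiplicative bleach factor shared with a LOV2-free
#' control trace (the control carries no switching term, and optionally a
#' small control-only fast-quench to exercise imperfect correction), and
#' adds independent Gaussian noise to both.
#'
#' @param spec A [generator_spec()] whose `truth` is a
#'   [photocycle_params()]. Protocol entries: `n_flashes` (20),
#'   `dark_times_s` ([default_dark_times()]), `dose_per_flash` (14),
#'   `flash_rate_hz` (4), `offset` (1), `control_fast_quench` (0).
#' @return An unnormalised [cycle_trace_set()] with control readings.
#' @export
gen_cycle_traces <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"),
            inherits(spec$truth, "photocycle_params"))
  n_flashes <- .proto(spec, "n_flashes", 20)
  dark <- .proto(spec, "dark_times_s", default_dark_times())
  dose <- .proto(spec, "dose_per_flash", 14)
  rate <- .proto(spec, "flash_rate_hz", 4)
  offset <- .proto(spec, "offset", 1)
  cfq <- .proto(spec, "control_fast_quench", 0)
  model <- trace_model_params(spec$truth, offset = offset,
                              flash_rate_hz = rate, dose_per_flash = dose)
  f <- if (spec$truth$mode == "donor") dequench_trace else quench_trace
  C <- length(dark)
  x <- 0:(n_flashes - 1)
  grid <- data.frame(cycle_index = rep(seq_len(C), each = n_flashes),
                     reading_index = rep(x, C))
  clean <- f(model, grid$reading_index, dark[grid$cycle_index])
  # control: no LOV2 term, optional small first-readings quench
  global_idx <- seq_len(nrow(grid)) - 1
  ctrl_clean <- offset * (1 - cfq * (1 - exp(-global_idx / 5)))
  bleach <- (1 - spec$bleach_per_reading)^global_idx
  .with_seed(spec$seed, {
    mk <- function(values, prefix) do.call(rbind, lapply(
      seq_len(spec$n_replicates), function(rep) {
        data.frame(sample_id = sprintf("%s%d", prefix, rep), grid,
                   intensity_au = values * bleach +
                     stats::rnorm(nrow(grid), 0, spec$noise_sd))
      }))
    readings <- mk(clean, "well")
    control <- mk(ctrl_clean, "ctrl")
    cycle_trace_set(readings, dark, dose, rate,
                    control_readings = control)
  })
}

#' Generate plate-reader dark-recovery traces
#'
#' Post-illumination recovery from dequench measured on cell lysates:
#' fluorescence rises from `F_limit * (1 - A_rel)` toward `F_limit` with
#' the truth's dark relaxation time constant, sampled over `n_cycles`
#' reader cycles of `cycle_s` seconds (defaults 20 x 3 s).
#'
#' @param spec A [generator_spec()] whose `truth` is a
#'   [photocycle_params()]. Protocol entries: `n_cycles` (20), `cycle_s`
#'   (3), `A_rel` (initial fractional dequench deficit, default the
#'   truth's transfer limit), `F_limit` (1).
#' @return Data.frame with columns `sample_id`, `time_s`, `intensity_au`.
#' @export
gen_dark_recovery_plate <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"),
            inherits(spec$truth, "photocycle_params"))
  n_cycles <- .proto(spec, "n_cycles", 20)
  cycle_s <- .proto(spec, "cycle_s", 3)
  A_rel <- .proto(spec, "A_rel", spec$truth$transfer_limit)
  F_limit <- .proto(spec, "F_limit", 1)
  t <- (seq_len(n_cycles) - 1) * cycle_s
  clean <- F_limit * (1 - A_rel * exp(-t / spec$truth$relaxation_s))
  .with_seed(spec$seed, do.call(rbind, lapply(
    seq_len(spec$n_replicates), function(rep)
      data.frame(sample_id = sprintf("well%d", rep), time_s = t,
                 intensity_au = clean +
                   stats::rnorm(length(t), 0, spec$noise_sd)))))
}

#' Generate nucleocytoplasmic-ratio series under flash trains
#'
#' Emulates light-driven nuclear export read by imaging: the ratio starts
#' at the (nuclear-biased) baseline and falls linearly during each flash
#' train at the per-flash rate `Max * dose / (ED50 + dose)`, fully
#' recovering between cycles (cycles are >= 10 min apart).
#'
#' @param spec A [generator_spec()] whose `truth` is
#'   `list(Max = ..., ED50 = ...)` (per-flash rate at saturation and
#'   half-effective per-flash dose). Protocol entries: `doses`
#'   (c(14, 42, 140, 420)), `n_flashes` (10), `n_cycles` (4), `baseline`
#'   (2.37). `noise_sd` is in ratio units here.
#' @return Data.frame with columns `sample_id`, `dose_per_flash_umol_m2`,
#'   `cycle_index`, `reading_index`, `nc_ratio`.
#' @export
gen_translocation_ratios <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"), is.list(spec$truth),
            all(c("Max", "ED50") %in% names(spec$truth)))
  doses <- .proto(spec, "doses", c(14, 42, 140, 420))
  n_flashes <- .proto(spec, "n_flashes", 10)
  n_cycles <- .proto(spec, "n_cycles", 4)
  baseline <- .proto(spec, "baseline", 2.37)
  x <- 0:(n_flashes - 1)
  .with_seed(spec$seed, do.call(rbind, lapply(
    seq_len(spec$n_replicates), function(rep) do.call(rbind, lapply(
      doses, function(dose) {
        rate <- spec$truth$Max * dose / (spec$truth$ED50 + dose)
        do.call(rbind, lapply(seq_len(n_cycles), function(cy)
          data.frame(sample_id = sprintf("well%d", rep),
                     dose_per_flash_umol_m2 = dose, cycle_index = cy,
                     reading_index = x,
                     nc_ratio = baseline - rate * x +
                       stats::rnorm(n_flashes, 0, spec$noise_sd))))
      })))))
}

#' Generate reporter series with alternating lit/dark phases
#'
#' Piecewise reporter-model curves: lit (reduction) phases decay from
#' `L + S` toward `L` with `tau_lit`; dark (recovery) phases rise back
#' with `tau_dark`, optionally under the relaxing-inhibitor forward rate.
#'
#' @param spec A [generator_spec()] whose `truth` is a list with `L`,
#'   `S`, `tau_lit`, `tau_dark` (and optionally `relaxing`, `kf_fraction`,
#'   `A_inhib`, `rho_s`). Protocol entries: `phase_s` (1200), `dt_s` (60),
#'   `n_pairs` (2; lit/dark pairs). `noise_sd` is in ratio units.
#' @return Data.frame with columns `sample_id`, `phase`, `phase_index`,
#'   `time_s`, `nc_ratio`.
#' @export
gen_reporter_series <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"), is.list(spec$truth),
            all(c("L", "S", "tau_lit", "tau_dark") %in% names(spec$truth)))
  tr <- spec$truth
  phase_s <- .proto(spec, "phase_s", 1200)
  dt_s <- .proto(spec, "dt_s", 60)
  n_pairs <- .proto(spec, "n_pairs", 2)
  relaxing <- isTRUE(tr$relaxing)
  t <- seq(0, phase_s, by = dt_s)
  lit_clean <- tr$L + tr$S * .phase_decay(t, tr$tau_lit)
  dark_clean <- tr$L + tr$S - tr$S *
    .phase_decay(t, tr$tau_dark, relaxing = relaxing,
                 kf_fraction = if (is.null(tr$kf_fraction)) 0.5 else
                   tr$kf_fraction,
                 A_inhib = if (is.null(tr$A_inhib)) 1 else tr$A_inhib,
                 rho_s = if (is.null(tr$rho_s)) 120 else tr$rho_s)
  .with_seed(spec$seed, do.call(rbind, lapply(
    seq_len(spec$n_replicates), function(rep) do.call(rbind, lapply(
      seq_len(n_pairs), function(pair) rbind(
        data.frame(sample_id = sprintf("well%d", rep), phase = "lit",
                   phase_index = 2 * pair - 1, time_s = t,
                   nc_ratio = lit_clean +
                     stats::rnorm(length(t), 0, spec$noise_sd)),
        data.frame(sample_id = sprintf("well%d", rep), phase = "dark",
                   phase_index = 2 * pair, time_s = t,
                   nc_ratio = dark_clean +
                     stats::rnorm(length(t), 0, spec$noise_sd))))))))
}
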