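# The first-order reversible LOV2 switching model and closed-form trace
# equations that all fitting and simulation reference.
#
# The model is the two-state approximation LOV-445 (dark) <-> LOV-390
# (cysteine adduct, "lit"). Blue light drives the forward reaction at rate
# k_f = flux / sensitivity; thermal relaxation reverses it at k_r = 1 / r.
# The apparent rate during illumination is k_app = k_f + k_r and the lit
# fraction approaches k_f / (k_f + k_r).

#' Photocycle parameters of a LOV2 actuator construct
#'
#' @param sensitivity Photon dose (umol m^-2) producing unit forward drive;
#'   the forward rate under flux phi (umol m^-2 s^-1) is phi / sensitivity.
#'   Must be > 0.
#' @param relaxation_s Dark relaxation time constant r in s; the reverse
#'   rate is k_r = 1 / r. Must be > 0.
#' @param transfer_limit Maximal fractional quench (acceptor mode) or
#'   dequench (donor mode) attributable to RET with dark-state LOV2, as a
#'   fraction in [0, 1]. Table values quoted in percent are converted at
#'   I/O, never stored.
#' @param mode `"donor"` (cyan tag quenched by dark LOV2; traces rise on
#'   activation) or `"acceptor"` (yellow/red tag sensitised by LOV2*;
#'   traces fall on activation).
#' @return An object of class `photocycle_params`.
#' @examples
#' photocycle_params(162, 6.8, 0.189, "donor")   # mTq2-optoNES scale
#' @export
photocycle_params <- function(sensitivity, relaxation_s, transfer_limit,
                              mode = c("donor", "acceptor")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(sensitivity), is.numeric(relaxation_s),
            is.numeric(transfer_limit))
  if (sensitivity <= 0) stop("sensitivity must be positive")
  if (relaxation_s <= 0) stop("relaxation_s must be positive")
  if (transfer_limit < 0 || transfer_limit > 1)
    stop("transfer_limit must be a fraction in [0, 1]")
  structure(list(sensitivity = sensitivity, relaxation_s = relaxation_s,
                 transfer_limit = transfer_limit, mode = mode),
            class = "photocycle_params")
}

#' @export
print.photocycle_params <- function(x, ...) {
  cat(sprintf(paste0("<photocycle_params> mode=%s sensitivity=%.4g umol m^-2",
                     " r=%.4g s transfer_limit=%.4g\n"),
              x$mode, x$sensitivity, x$relaxation_s, x$transfer_limit))
  invisible(x)
}

#' Trace-model parameters for cycle fitting and simulation
#'
#' Bundles photocycle constants with the acquisition protocol: the overall
#' fluorescence offset (fitted plateau scale) and the flash schedule. The
#' time-averaged flux during an illumination phase is
#' `flash_rate_hz * dose_per_flash`; the hard-coded 56 and 560
#' umol m^-2 s^-1 of the plate protocols are 4 Hz times 14 or 140
#' umol m^-2 per flash.
#'
#' @param photocycle A [photocycle_params()] object.
#' @param offset Fluorescence scale factor (arbitrary units, > 0);
#'   traces normalised to their first point have offset near 1.
#' @param flash_rate_hz Readings (= flashes) per second; default 4.
#' @param dose_per_flash Photon dose per flash, umol m^-2 (>= 0).
#' @return An object of class `trace_model_params`.
#' @export
trace_model_params <- function(photocycle, offset = 1, flash_rate_hz = 4,
                               dose_per_flash = 14) {
  stopifnot(inherits(photocycle, "photocycle_params"))
  if (offset <= 0) stop("offset must be positive")
  if (flash_rate_hz <= 0) stop("flash_rate_hz must be positive")
  if (dose_per_flash < 0) stop("dose_per_flash must be non-negative")
  structure(list(photocycle = photocycle, offset = offset,
                 flash_rate_hz = flash_rate_hz,
                 dose_per_flash = dose_per_flash),
            class = "trace_model_params")
}

#' Forward, reverse and apparent rate constants under a given flux
#'
#' @param flux Photon flux in umol m^-2 s^-1 (>= 0), or a [photon_flux()].
#' @param params A [photocycle_params()] object.
#' @return List with `k_f`, `k_r` and `k_app = k_f + k_r`, all in s^-1.
#' @examples
#' forward_rate(56, photocycle_params(162, 6.8, 0.189))
#' @export
forward_rate <- function(flux, params) {
  v <- if (inherits(flux, "photon_flux")) flux$value else flux
  stopifnot(is.numeric(v), inherits(params, "photocycle_params"))
  if (any(v < 0)) stop("flux must be non-negative")
  k_f <- v / params$sensitivity
  k_r <- 1 / params$relaxation_s
  list(k_f = k_f, k_r = k_r, k_app = k_f + k_r)
}

#' Equilibrium lit-state fraction under constant flux
#'
#' The steady-state adduct fraction k_f / (k_f + k_r); the equilibrium
#' transfer change is `transfer_limit` times this fraction.
#'
#' @inheritParams forward_rate
#' @return Fraction in [0, 1).
#' @export
equilibrium_fraction <- function(flux, params) {
  k <- forward_rate(flux, params)
  ifelse(k$k_f == 0, 0, k$k_f / (k$k_f + k$k_r))
}

#' Apparent (relaxation-contaminated) activation sensitivity
#'
#' The observed dose scale of activation, flux / k_app: smaller than the
#' true sensitivity because relaxation proceeds during illumination.
#'
#' @inheritParams forward_rate
#' @return Apparent sensitivity in umol m^-2; always < `sensitivity`.
#' @export
apparent_sensitivity <- function(flux, params) {
  v <- if (inherits(flux, "photon_flux")) flux$value else flux
  if (any(v <= 0)) stop("flux must be positive for apparent sensitivity")
  k <- forward_rate(v, params)
  v / k$k_app
}

#' Half-maximal per-flash photon dose (ED50)
#'
#' The per-flash dose at which, delivered at `flash_rate_hz`, the forward
#' drive equals the relaxation rate (k_f = k_r), so equilibrium switching
#' is half the transfer limit: ED50 = sensitivity / (flash_rate * r).
#'
#' @param params A [photocycle_params()] object.
#' @param flash_rate_hz Flash rate in Hz; default 4 (the plate protocol).
#' @return ED50 in umol m^-2 per flash.
#' @examples
#' ed50(photocycle_params(203, 14.4, 0.176))  # ~3.5
#' @export
ed50 <- function(params, flash_rate_hz = 4) {
  stopifnot(inherits(params, "photocycle_params"))
  if (flash_rate_hz <= 0) stop("flash_rate_hz must be positive")
  params$sensitivity / (flash_rate_hz * params$relaxation_s)
}

# shared kernel of the cycle trace equations: equilibrium amplitude and the
# recovery/re-equilibration factor. x = reading index within the cycle
# (0-based), t = preceding dark time in s.
.cycle_kernel <- function(model, reading_index, dark_time_s) {
  p <- model$photocycle
  flux <- model$flash_rate_hz * model$dose_per_flash
  k <- forward_rate(flux, p)
  eq_frac <- if (k$k_f == 0) 0 else k$k_f / (k$k_f + k$k_r)
  m_max <- p$transfer_limit * eq_frac  # D_max[dose] or Q_max[dose]
  recov <- (1 - exp(-dark_time_s / p$relaxation_s)) *
    exp(-k$k_app * reading_index / model$flash_rate_hz)
  list(m_max = m_max, recov = recov)
}

#' Donor dequench trace during an activation cycle
#'
#' Normalised fluorescence of a donor-mode construct at reading `x` of a
#' cycle preceded by `dark_time_s` of darkness:
#' \deqn{Y = Offset (1 - D_{limit} + D_{max}[dose]
#'       (1 - (1 - e^{-t/r}) e^{-k_{app} x / rate}))}
#' with \eqn{D_{max}[dose] = D_{limit} / (1 + k_r/k_f)}. The trace rises
#' from the relaxed, maximally quenched level `Offset * (1 - D_limit)`
#' toward the illumination equilibrium.
#'
#' @param model A [trace_model_params()] with a donor-mode photocycle.
#' @param reading_index 0-based reading (= flash) index within the cycle.
#' @param dark_time_s Dark time preceding the cycle, s.
#' @return Normalised fluorescence, vectorised over `reading_index` and
#'   `dark_time_s`.
#' @export
dequench_trace <- function(model, reading_index, dark_time_s) {
  stopifnot(inherits(model, "trace_model_params"))
  if (model$photocycle$mode != "donor")
    stop("dequench_trace requires donor-mode params; got acceptor")
  if (any(reading_index < 0)) stop("reading_index must be >= 0")
  if (any(dark_time_s < 0)) stop("dark_time_s must be >= 0")
  kk <- .cycle_kernel(model, reading_index, dark_time_s)
  model$offset *
    (1 - model$photocycle$transfer_limit + kk$m_max * (1 - kk$recov))
}

#' Acceptor quench trace during an activation cycle
#'
#' Mirror of [dequench_trace()] for acceptor-mode constructs: the trace
#' falls from the fully sensitised level `Offset` (dark-adapted, x = 0)
#' toward `Offset * (1 - Q_max[dose])` under illumination.
#'
#' @inheritParams dequench_trace
#' @param model A [trace_model_params()] with an acceptor-mode photocycle.
#' @export
quench_trace <- function(model, reading_index, dark_time_s) {
  stopifnot(inherits(model, "trace_model_params"))
  if (model$photocycle$mode != "acceptor")
    stop("quench_trace requires acceptor-mode params; got donor")
  if (any(reading_index < 0)) stop("reading_index must be >= 0")
  if (any(dark_time_s < 0)) stop("dark_time_s must be >= 0")
  kk <- .cycle_kernel(model, reading_index, dark_time_s)
  model$offset * (1 - kk$m_max * (1 - kk$recov))
}

#' Per-cycle exponential of the two-stage fit
#'
#' The descriptive model of a single activation cycle,
#' `F[x] = F_limit - A[cycle] * exp(-x / tau_flashes)`, with one shared
#' activation constant `tau_flashes` (in flashes) and a cycle-specific
#' amplitude.
#'
#' @param F_limit Fitted fluorescence limit as flash count grows.
#' @param A Amplitudes per cycle (recovery from (de)quenching after each
#'   dark period); all >= 0.
#' @param tau_flashes Shared activation constant in flashes (> 0).
#' @param cycle 1-based cycle index into `A`.
#' @param reading 0-based reading index within the cycle.
#' @return Fluorescence value(s).
#' @export
cycle_exponential <- function(F_limit, A, tau_flashes, cycle, reading) {
  if (tau_flashes <= 0) stop("tau_flashes must be positive")
  if (any(A < 0)) stop("amplitudes must be non-negative")
  if (any(cycle < 1) || any(cycle > length(A)))
    stop("cycle index out of range")
  if (any(reading < 0)) stop("reading must be >= 0")
  F_limit - A[cycle] * exp(-reading / tau_flashes)
}

#' Dark-recovery amplitude as a function of dark time
#'
#' `A[t] = A0 * (1 - exp(-t / r))`: the recovered (de)quench amplitude
#' after `t` seconds of darkness, saturating at `A0`.
#'
#' @param A0 Maximal recovery amplitude (fraction of the fluorescence
#'   limit), >= 0.
#' @param r Relaxation time constant in s (> 0).
#' @param dark_time_s Dark time(s) in s (>= 0).
#' @return Amplitude(s), monotone increasing in `dark_time_s`.
#' @export
dark_recovery_amplitude <- function(A0, r, dark_time_s) {
  if (any(A0 < 0)) stop("A0 must be non-negative")
  if (r <= 0) stop("r must be positive")
  if (any(dark_time_s < 0)) stop("dark_time_s must be >= 0")
  A0 * (1 - exp(-dark_time_s / r))
}

#' Maximal (de)quench percentage implied by a recovery amplitude
#'
#' Converts the fitted maximal recovery amplitude A0 (expressed relative
#' to the illuminated fluorescence limit) into the maximal fractional
#' change of the dark-adapted signal: `100 * A0 / (1 + A0)` percent.
#'
#' @param A0 Maximal recovery amplitude, >= 0.
#' @return Percentage in [0, 100).
#' @examples
#' max_dequench_percent(0.19)  # ~16
#' @export
max_dequench_percent <- function(A0) {
  if (any(A0 < 0)) stop("A0 must be non-negative")
  100 * A0 / (1 + A0)
}
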