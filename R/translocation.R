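# Downstream-readout analyses: per-flash nuclear-export rates and their
# photon-dose response, and the bidirectional kinetics of a kinase
# translocation reporter under alternating lit/dark phases, including the
# inhibitor-relaxation-corrected forward-rate variant.

#' Per-flash nuclear export rate from a ratio series
#'
#' Ordinary least-squares slope of the nuclear:cytoplasmic ratio against
#' flash number within an illumination window: the rate of light-driven
#' export per flash at the given dose.
#'
#' @param series Data.frame with columns `reading_index` (flash number)
#'   and `nc_ratio`.
#' @return List with `gradient` (ratio change per flash), `offset` and
#'   `se` of the gradient.
#' @export
export_rate <- function(series) {
  series <- as.data.frame(series)
  stopifnot(all(c("reading_index", "nc_ratio") %in% names(series)))
  if (nrow(series) < 3)
    stop("insufficient data: need >= 3 points in the flash window")
  fit <- stats::lm(nc_ratio ~ reading_index, data = series)
  s <- summary(fit)$coefficients
  list(gradient = unname(s["reading_index", "Estimate"]),
       offset = unname(s["(Intercept)", "Estimate"]),
       se = unname(s["reading_index", "Std. Error"]))
}

#' Dose-response of export rates to per-flash photon dose
#'
#' Fits the per-dose export rates to the single-site saturation model
#' `Response = Max * dose / (ED50 + dose)`. With a grouping column,
#' groups share `Max` and fit separate ED50s, so sensitivity differences
#' can be tested with [nested_f_test()] against the `shared_ed50`
#' restricted fit. Optional normalisation divides responses by the fitted
#' group maximum; it does not change the fitted ED50.
#'
#' @param gradients Data.frame with columns `dose` and `rate` (and
#'   optionally `group`).
#' @param normalize Also return rates normalised to the fitted `Max`.
#' @param shared_ed50 Fit the restricted one-ED50 model instead.
#' @return A `fit_result`; with `normalize`, an extra `normalized_rates`
#'   data.frame is attached.
#' @export
dose_response <- function(gradients, normalize = FALSE,
                          shared_ed50 = FALSE) {
  gradients <- as.data.frame(gradients)
  stopifnot(all(c("dose", "rate") %in% names(gradients)))
  grp <- if ("group" %in% names(gradients)) gradients$group else NULL
  if (length(unique(gradients$dose)) < 3)
    stop("insufficient data: need >= 3 doses")
  if (stats::sd(gradients$rate) < 1e-14 * max(abs(gradients$rate), 1))
    stop("degenerate fit: responses do not vary")
  res <- fit_single_site(gradients$dose, gradients$rate, group = grp,
                         shared_ed50 = shared_ed50)
  res$model <- "dose_response"
  if (normalize) {
    a <- res$params["max", "best_fit"]
    res$normalized_rates <- data.frame(gradients,
                                       rate_norm = gradients$rate / a)
  }
  res
}

#' Reporter kinetics parameter set
#'
#' @param baseline Asymptotic ratio level.
#' @param span Initial deviation from baseline (ratio units).
#' @param k_f,k_r Forward (phosphorylation-driven) and reverse rate
#'   constants, s^-1, both >= 0.
#' @param A_inhib Maximal fractional reduction of `k_f` by the optogenetic
#'   inhibitor, in [0, 1].
#' @param rho_s Inhibitor relaxation time constant, s (~120 s for the
#'   slow-relaxing inhibitor).
#' @return An object of class `reporter_kinetics`.
#' @export
reporter_kinetics <- function(baseline, span, k_f, k_r, A_inhib = 0,
                              rho_s = 120) {
  if (k_f < 0 || k_r < 0) stop("rates must be non-negative")
  if (A_inhib < 0 || A_inhib > 1) stop("A_inhib must lie in [0, 1]")
  if (rho_s <= 0) stop("rho_s must be positive")
  structure(list(baseline = baseline, span = span, k_f = k_f, k_r = k_r,
                 A_inhib = A_inhib, rho_s = rho_s),
            class = "reporter_kinetics")
}

#' Reporter relaxation with optional inhibitor-corrected forward rate
#'
#' Uninhibited, the reporter relaxes as
#' `baseline + span * exp(-(k_f + k_r) t)`. When the optogenetic
#' inhibitor decays with time constant `rho_s`, the forward rate becomes
#' `(1 - A_inhib * exp(-t / rho_s)) * k_f`, giving the closed-form
#' exponent `-( (k_f + k_r) t - k_f * A_inhib * rho_s *
#' (1 - exp(-t / rho_s)) )`.
#'
#' @param kin A [reporter_kinetics()].
#' @param t Time(s) since the phase start, s (>= 0).
#' @param inhibited Apply the relaxing-inhibitor correction.
#' @return Ratio value(s).
#' @export
reporter_model <- function(kin, t, inhibited = FALSE) {
  stopifnot(inherits(kin, "reporter_kinetics"))
  if (any(t < 0)) stop("t must be >= 0")
  k_sum <- kin$k_f + kin$k_r
  expo <- if (inhibited)
    -(k_sum * t - kin$k_f * kin$A_inhib * kin$rho_s *
        (1 - exp(-t / kin$rho_s)))
  else -k_sum * t
  kin$baseline + kin$span * exp(expo)
}

# effective decay factor for a phase: plain exponential, or with the
# relaxing-k_f time warp t -> t - phi * A * rho * (1 - exp(-t/rho))
.phase_decay <- function(t, tau, relaxing = FALSE, kf_fraction = 0.5,
                         A_inhib = 1, rho_s = 120) {
  te <- if (relaxing)
    t - kf_fraction * A_inhib * rho_s * (1 - exp(-t / rho_s))
  else t
  exp(-te / tau)
}

#' Fit lit/dark reporter phases with shared spans
#'
#' Averages and fits the labelled reduction (lit) and recovery (dark)
#' phases of a reporter series to exponential approaches toward a common
#' pair of levels: lit phases decay from `L + S` toward `L` with time
#' constant `tau_lit`, dark phases recover toward `L + S` with `tau_dark`.
#' With `share_span` (default, matching the joint-comparison workflow)
#' one span `S` is shared between the two phase classes; otherwise each
#' class gets its own span. A restricted equal-tau fit is also computed,
#' and the two are compared with the extra-sum-of-squares F test.
#'
#' @param series Data.frame with columns `phase` (`"lit"`/`"dark"`),
#'   `time_s` (since phase start) and `nc_ratio`. Multiple phase repeats
#'   may be stacked; they are fitted jointly.
#' @param share_span One shared span across phase classes (default TRUE).
#' @param use_relaxing_kf Replace the lit-phase-driving forward rate in
#'   the dark (recovery) phases by the relaxing form
#'   `(1 - A_inhib exp(-t/rho)) k_f` with fixed `rho_s`, `A_inhib` and
#'   forward-rate share `kf_fraction`; default FALSE.
#' @param rho_s,A_inhib,kf_fraction Relaxing-inhibitor constants (s,
#'   fraction, fraction); used only when `use_relaxing_kf = TRUE`.
#' @return List with `fit` (full, distinct taus), `fit_equal_tau`
#'   (restricted), `tau` (named c(lit, dark)) and `f_test`.
#' @export
fit_reporter_phases <- function(series, share_span = TRUE,
                                use_relaxing_kf = FALSE, rho_s = 120,
                                A_inhib = 0.5, kf_fraction = 0.5) {
  series <- as.data.frame(series)
  stopifnot(all(c("phase", "time_s", "nc_ratio") %in% names(series)))
  if (!all(series$phase %in% c("lit", "dark")))
    stop("protocol error: phases must be labelled 'lit' or 'dark'")
  for (ph in c("lit", "dark"))
    if (sum(series$phase == ph) < 3)
      stop("protocol error: need >= 3 points per phase class")
  lit <- series$phase == "lit"
  t <- series$time_s
  y <- series$nc_ratio

  values <- function(L, S_lit, S_dark, tau_lit, tau_dark) {
    e_lit <- .phase_decay(t[lit], tau_lit)
    e_dark <- .phase_decay(t[!lit], tau_dark, relaxing = use_relaxing_kf,
                           kf_fraction = kf_fraction, A_inhib = A_inhib,
                           rho_s = rho_s)
    out <- numeric(length(t))
    out[lit] <- L + S_lit * e_lit
    out[!lit] <- L + S_dark - S_dark * e_dark
    out
  }
  t_scale <- max(t)
  mk_fn <- function(equal_tau) function(theta) {
    L <- theta[1]; S1 <- theta[2]
    S2 <- if (share_span) S1 else theta[3]
    i <- if (share_span) 3 else 4
    tau_l <- theta[i]
    tau_d <- if (equal_tau) theta[i] else theta[i + 1]
    values(L, S1, S2, tau_l, tau_d) - y
  }
  span0 <- max(y) - min(y)
  mk_starts <- function(equal_tau) lapply(
    t_scale * c(0.1, 0.3, 1), function(tau0)
      c(min(y), span0, if (!share_span) span0, tau0,
        if (!equal_tau) tau0))
  np <- function(equal_tau) 2 + (!share_span) + 2 - equal_tau
  fit_one <- function(equal_tau, model_name) {
    n <- np(equal_tau)
    fit <- .lm_multistart(mk_fn(equal_tau), mk_starts(equal_tau),
                          lower = c(-Inf, -Inf, if (!share_span) -Inf,
                                    rep(1e-6, 2 - equal_tau)),
                          upper = rep(Inf, n))
    nm <- c("L", if (share_span) "S" else c("S_lit", "S_dark"),
            if (equal_tau) "tau" else c("tau_lit", "tau_dark"))
    .make_fit_result(fit, nm, n_points = length(y), model = model_name)
  }
  full <- fit_one(FALSE, "reporter_phases")
  restricted <- fit_one(TRUE, "reporter_phases_equal_tau")
  th <- coef(full)
  list(fit = full, fit_equal_tau = restricted,
       tau = c(lit = unname(th["tau_lit"]), dark = unname(th["tau_dark"])),
       f_test = nested_f_test(restricted, full))
}
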