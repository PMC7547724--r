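# Shared-parameter nonlinear least-squares fitting of normalised traces
# to the photocycle models.
#
# Two routes to the same constants:
#  * two-stage: per-cycle exponentials with one shared activation constant
#    (fit_cycle_exponentials), then the amplitudes against dark time
#    (fit_dark_relaxation);
#  * global: one joint fit of offset, transfer limit, sensitivity and
#    relaxation time over every reading of every cycle
#    (fit_global_switch).
# Replicate repeats of the same protocol are averaged per reading before
# fitting by default, matching the plate workflow.

# delta-method SE of g(theta) given gradient and covariance
.delta_se <- function(grad, cov) {
  if (is.null(cov)) return(NA_real_)
  sqrt(max(0, drop(t(grad) %*% cov %*% grad)))
}

.require_normalized <- function(traces) {
  if (!traces$normalized)
    stop("traces must be normalised first (see normalize_to_control)")
}

# apply the drop-first convention: discard the very first reading of each
# sample's session (a systematic artefact of imperfect control correction)
.apply_drop_first <- function(rd) {
  first_cycle <- min(rd$cycle_index)
  !(rd$cycle_index == first_cycle & rd$reading_index == 0)
}

#' Two-stage step 1: per-cycle exponentials with a shared activation rate
#'
#' Fits `F[x] = F_limit - A[cycle] * exp(-x / tau_flashes)` jointly over
#' all cycles: one shared fluorescence limit and activation constant
#' (in flashes), one amplitude per cycle.
#'
#' @param traces A normalised [cycle_trace_set()].
#' @param drop_first Discard the first reading of the session (see the
#'   dose-series workflow); default FALSE.
#' @param average Average replicate samples per reading before fitting
#'   (default TRUE).
#' @return A `fit_result` with parameters `F_limit`, `tau_flashes` and
#'   `A[1]`..`A[C]`, plus derived `k_app_per_flash = 1 / tau_flashes`.
#' @export
fit_cycle_exponentials <- function(traces, drop_first = FALSE,
                                   average = TRUE) {
  stopifnot(inherits(traces, "cycle_trace_set"))
  .require_normalized(traces)
  rd <- if (average) .average_replicates(traces$readings) else
    traces$readings
  if (drop_first) {
    rd <- rd[.apply_drop_first(rd), ]
    if (length(unique(rd$cycle_index)) < 2)
      warning("single cycle after drop_first: degrees of freedom reduced")
  }
  cycles <- sort(unique(rd$cycle_index))
  C <- length(cycles)
  if (C < 1) stop("insufficient data: no cycles")
  ci <- match(rd$cycle_index, cycles)
  x <- rd$reading_index
  y <- rd$intensity_au

  model <- function(theta) {
    F_limit <- theta[1]; tau <- theta[2]; A <- theta[3:(2 + C)]
    F_limit - A[ci] * exp(-x / tau)
  }
  fn <- function(theta) model(theta) - y

  # heuristic starts: limit from the trace span, tau from log-linear
  # regression of the largest cycle, amplitudes from first-reading deficit
  F0 <- max(y)
  A0 <- vapply(seq_len(C), function(c)
    max(F0 - y[ci == c][which.min(x[ci == c])], 1e-4), 0)
  tau_grid <- c(3, 8, 20)
  big <- which.max(A0)
  d <- F0 * 1.001 - y[ci == big]
  ok <- d > 0
  if (sum(ok) >= 3) {
    sl <- stats::coef(stats::lm(log(d[ok]) ~ x[ci == big][ok]))[2]
    if (is.finite(sl) && sl < 0) tau_grid <- c(-1 / sl, tau_grid)
  }
  starts <- lapply(tau_grid, function(tau) c(F0, tau, A0))
  fit <- .lm_multistart(fn, starts,
                        lower = c(0, 1e-6, rep(0, C)),
                        upper = c(Inf, Inf, rep(Inf, C)))
  res <- .make_fit_result(
    fit, c("F_limit", "tau_flashes", paste0("A[", cycles, "]")),
    n_points = length(y), model = "cycle_exponentials")
  res$derived <- list(k_app_per_flash = 1 / fit$theta[2])
  res$cycles <- cycles
  res
}

#' Two-stage step 2: dark relaxation from recovery amplitudes
#'
#' Fits the recovered amplitudes against preceding dark time,
#' `A[t] = A0 * (1 - exp(-t / r))` (optionally with a free baseline for
#' raw plate recovery traces), giving the dark relaxation time constant
#' and the maximal dequench percentage `100 * A0 / (1 + A0)`.
#'
#' @param amplitudes Data.frame with columns `dark_time_s` and `A`
#'   (and optionally `se`, carried through but not used as weights).
#'   Sentinel dark times >= 600 s are treated as effectively infinite
#'   recovery and included as-is.
#' @param baseline `"zero"` (amplitudes start at 0, the default) or
#'   `"fit"` (adds a free offset, for raw recovery traces).
#' @return A `fit_result` with `A0`, `r` (and `F0` when fitted), derived
#'   `max_dequench_pct` with a delta-method SE.
#' @export
fit_dark_relaxation <- function(amplitudes, baseline = c("zero", "fit")) {
  baseline <- match.arg(baseline)
  amplitudes <- as.data.frame(amplitudes)
  stopifnot(all(c("dark_time_s", "A") %in% names(amplitudes)))
  t <- amplitudes$dark_time_s; A <- amplitudes$A
  if (length(unique(t)) < 3)
    stop("insufficient data: need >= 3 distinct dark times")
  if (stats::sd(A) < 1e-12 * max(abs(A), 1)) {
    res <- structure(list(model = "dark_relaxation",
                          params = data.frame(best_fit = c(NA, NA),
                                              se = c(NA, NA),
                                              row.names = c("A0", "r")),
                          dof = length(A) - 2, ssr = 0, n_points = length(A),
                          derived = list(), converged = FALSE,
                          flags = "non_identifiable: all amplitudes equal",
                          cov = NULL),
                     class = "fit_result")
    return(res)
  }
  with_f0 <- baseline == "fit"
  fn <- function(theta) {
    A0 <- theta[1]; r <- theta[2]
    f0 <- if (with_f0) theta[3] else 0
    f0 + A0 * (1 - exp(-t / r)) - A
  }
  r_grid <- c(2, 7, 20, 60)
  A_top <- max(A) - if (with_f0) min(A) else 0
  starts <- lapply(r_grid, function(r)
    c(max(A_top, 1e-3), r, if (with_f0) min(A)))
  fit <- .lm_multistart(fn, starts,
                        lower = c(0, 1e-6, if (with_f0) -Inf),
                        upper = c(Inf, Inf, if (with_f0) Inf))
  nm <- c("A0", "r", if (with_f0) "F0")
  res <- .make_fit_result(fit, nm, n_points = length(A),
                          model = "dark_relaxation")
  A0h <- fit$theta[1]
  grad <- c(100 / (1 + A0h)^2, rep(0, length(nm) - 1))
  res$derived <- list(
    max_dequench_pct = list(value = max_dequench_percent(A0h),
                            se = .delta_se(grad, res$cov)))
  res
}

# trace model over a cycle set for given (offset, limit, sens, r)
.switch_model_values <- function(theta, mode, rd, dark_of, dose, rate) {
  p <- photocycle_params(theta[3], theta[4], theta[2], mode)
  m <- trace_model_params(p, offset = theta[1], flash_rate_hz = rate,
                          dose_per_flash = dose)
  f <- if (mode == "donor") dequench_trace else quench_trace
  f(m, rd$reading_index, dark_of[as.character(rd$cycle_index)])
}

#' Global joint fit of the reversible switching model to cycle traces
#'
#' Fits offset, transfer limit, sensitivity and dark relaxation time in a
#' single least-squares pass over every reading of every cycle, using the
#' closed-form dequench (donor) or quench (acceptor) trace equation.
#' Derived quantities: `ed50_umol_m2_per_flash = sensitivity /
#' (flash_rate * r)` (with delta-method SE), the apparent sensitivity at
#' the protocol flux, and the maximal dequench percentage at this dose.
#'
#' @param traces A normalised [cycle_trace_set()].
#' @param mode `"donor"` or `"acceptor"`.
#' @param average Average replicates per reading first (default TRUE).
#'   When FALSE, replicates are fitted jointly.
#' @param retry_on_average When TRUE (default) a failed or non-converged
#'   replicate-wise fit is retried on the replicate mean and flagged
#'   `refit_on_replicate_mean` (the low-signal fallback).
#' @return A `fit_result` with parameters `offset`, `transfer_limit`,
#'   `sensitivity`, `r`.
#' @export
fit_global_switch <- function(traces, mode = c("donor", "acceptor"),
                              average = TRUE, retry_on_average = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(traces, "cycle_trace_set"))
  .require_normalized(traces)
  run <- function(rd) {
    dark_of <- stats::setNames(traces$dark_times_s,
                               sort(unique(rd$cycle_index)))
    y <- rd$intensity_au
    fn <- function(theta)
      .switch_model_values(theta, mode, rd, dark_of,
                           traces$dose_per_flash, traces$flash_rate_hz) - y
    span <- max(y) - min(y)
    lim0 <- min(0.95, max(2 * span, 0.02))
    starts <- list()
    for (r0 in c(3, 8, 20))
      for (s0 in traces$dose_per_flash * traces$flash_rate_hz * r0 *
             c(0.5, 2))
        starts[[length(starts) + 1L]] <- c(1, lim0, s0, r0)
    fit <- .lm_multistart(fn, starts,
                          lower = c(1e-6, 0, 1e-6, 1e-6),
                          upper = c(Inf, 1, Inf, Inf))
    .make_fit_result(fit, c("offset", "transfer_limit", "sensitivity", "r"),
                     n_points = length(y), model = "global_switch")
  }
  rd <- if (average) .average_replicates(traces$readings) else
    traces$readings
  res <- tryCatch(run(rd), error = function(e) e)
  fellback <- FALSE
  if ((inherits(res, "error") || !res$converged) && !average &&
      retry_on_average) {
    res <- run(.average_replicates(traces$readings))
    fellback <- TRUE
  }
  if (inherits(res, "error")) stop(res)
  th <- res$params$best_fit
  names(th) <- rownames(res$params)
  flux <- traces$dose_per_flash * traces$flash_rate_hz
  pc <- photocycle_params(th["sensitivity"], th["r"], th["transfer_limit"],
                          mode)
  ed <- ed50(pc, traces$flash_rate_hz)
  # d(ed50)/d(offset, limit, sens, r)
  grad <- c(0, 0, 1 / (traces$flash_rate_hz * th["r"]),
            -th["sensitivity"] / (traces$flash_rate_hz * th["r"]^2))
  eqf <- equilibrium_fraction(flux, pc)
  m_max <- th["transfer_limit"] * eqf
  res$derived <- list(
    ed50_umol_m2_per_flash = list(value = ed, se = .delta_se(grad, res$cov)),
    apparent_sensitivity_umol_m2 = apparent_sensitivity(flux, pc),
    max_dequench_pct = 100 * m_max / (1 - th["transfer_limit"] + m_max))
  if (fellback) res$flags <- c(res$flags, "refit_on_replicate_mean")
  res$mode <- mode
  res
}

#' Joint first-order reversible fit across a photon-dose series
#'
#' Fits the activation traces recorded at several per-flash doses jointly
#' to the reversible two-state model: shared plateau, transfer limit,
#' sensitivity (1/k1) and relaxation time (1/k-1), with a dose-specific
#' apparent rate per curve.
#'
#' @param curves Data.frame with columns `dose_per_flash_umol_m2`,
#'   `reading_index` and `intensity_au` (replicates averaged beforehand or
#'   passed as extra rows; all rows are fitted).
#' @param mode `"donor"` or `"acceptor"`.
#' @param flash_rate_hz Reading rate, Hz (default 4).
#' @param drop_first Discard the first reading of each dose curve.
#' @return A `fit_result` with `plateau`, `transfer_limit`, `sensitivity`,
#'   `r`, plus derived per-flash ED50.
#' @export
fit_reversible_dose_series <- function(curves,
                                       mode = c("donor", "acceptor"),
                                       flash_rate_hz = 4,
                                       drop_first = FALSE) {
  mode <- match.arg(mode)
  curves <- as.data.frame(curves)
  need <- c("dose_per_flash_umol_m2", "reading_index", "intensity_au")
  stopifnot(all(need %in% names(curves)))
  if (drop_first) curves <- curves[curves$reading_index > 0, ]
  doses <- sort(unique(curves$dose_per_flash_umol_m2))
  if (length(doses) < 3) stop("insufficient data: need >= 3 doses")
  x <- curves$reading_index
  dose <- curves$dose_per_flash_umol_m2
  y <- curves$intensity_au

  model <- function(theta) {
    plateau <- theta[1]; lim <- theta[2]; sens <- theta[3]; r <- theta[4]
    kf <- dose / sens                   # per flash
    kr <- 1 / (r * flash_rate_hz)       # per flash
    kapp <- kf + kr
    m_max <- lim * kf / kapp
    if (mode == "donor")
      plateau * (1 - lim + m_max * (1 - exp(-kapp * x)))
    else
      plateau * (1 - m_max * (1 - exp(-kapp * x)))
  }
  fn <- function(theta) model(theta) - y
  span <- max(y) - min(y)
  lim0 <- min(0.95, max(2 * span, 0.02))
  starts <- list()
  for (r0 in c(2, 5, 15))
    for (s0 in stats::median(dose) * flash_rate_hz * r0 * c(0.5, 2))
      starts[[length(starts) + 1L]] <- c(max(y), lim0, s0, r0)
  fit <- .lm_multistart(fn, starts, lower = c(1e-6, 0, 1e-6, 1e-6),
                        upper = c(Inf, 1, Inf, Inf))
  res <- .make_fit_result(fit, c("plateau", "transfer_limit",
                                 "sensitivity", "r"),
                          n_points = length(y),
                          model = "reversible_dose_series")
  grad <- c(0, 0, 1 / (flash_rate_hz * fit$theta[4]),
            -fit$theta[3] / (flash_rate_hz * fit$theta[4]^2))
  res$derived <- list(
    ed50_umol_m2_per_flash = list(
      value = fit$theta[3] / (flash_rate_hz * fit$theta[4]),
      se = .delta_se(grad, res$cov)),
    k1_inv_umol_m2 = fit$theta[3], k_minus1_inv_s = fit$theta[4])
  res
}

#' Single-site (rectangular hyperbola) dose-response fit
#'
#' Fits `y = a / (1 + b / x) = a x / (b + x)`: `a` is the maximal
#' response, `b` the 50% effective photon dose (ED50). With a grouping
#' factor, groups share the maximum `a` and fit separate `b` by default
#' (`shared_ed50 = TRUE` restricts to one common `b`, the nested model
#' for the extra-sum-of-squares F test).
#'
#' @param x Photon doses (umol m^-2), > 0.
#' @param y Responses (any sign).
#' @param group Optional grouping factor, same length as `x`.
#' @param shared_ed50 Force one common ED50 across groups (restricted
#'   model); default FALSE.
#' @return A `fit_result` with `max` and `ed50` (per group when split).
#' @export
fit_single_site <- function(x, y, group = NULL, shared_ed50 = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (any(!is.finite(y))) stop("responses must be finite")
  if (any(x <= 0)) stop("doses must be positive")
  if (length(unique(x)) < 3) stop("insufficient data: need >= 3 doses")
  if (stats::sd(y) < 1e-14 * max(abs(y), 1) && all(y == 0))
    stop("degenerate fit: all responses zero")
  g <- if (is.null(group)) factor(rep(1, length(x))) else factor(group)
  G <- nlevels(g)
  one_b <- shared_ed50 || G == 1
  nb <- if (one_b) 1L else G
  gi <- as.integer(g)
  model <- function(theta) {
    a <- theta[1]; b <- theta[-1]
    bv <- if (one_b) rep(b[1], length(x)) else b[gi]
    a * x / (bv + x)
  }
  fn <- function(theta) model(theta) - y
  a0 <- y[which.max(x)] * 1.2
  if (a0 == 0) a0 <- max(abs(y)) * sign(sum(y) + 1e-300)
  starts <- lapply(c(0.3, 1, 3), function(f)
    c(a0, rep(stats::median(x) * f, nb)))
  fit <- .lm_multistart(fn, starts, lower = c(-Inf, rep(1e-9, nb)),
                        upper = rep(Inf, 1 + nb))
  nm <- c("max", if (one_b) "ed50" else paste0("ed50[", levels(g), "]"))
  res <- .make_fit_result(fit, nm, n_points = length(y),
                          model = "single_site")
  res
}
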