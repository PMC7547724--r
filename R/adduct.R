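# Adduct-state simulator: predicts the fraction of actuator in the
# cysteine-adduct (activated, LOV-390) state under arbitrary illumination
# trains. Used to design minimal-light protocols: the piecewise-constant
# flux makes the two-state ODE dA/dt = k_f(t) (1 - A) - A / r exactly
# solvable segment by segment, so `simulate_adduct` is exact for any dt.

#' An illumination schedule of timed flashes
#'
#' Either an explicit list of non-overlapping constant-flux events or a
#' periodic specification (a flash of fixed dose and duration repeated
#' every `period_s`).
#'
#' @param events Matrix or data.frame with columns `start`, `duration`,
#'   `flux` (s, s, umol m^-2 s^-1). Events must be sorted and
#'   non-overlapping; `duration > 0` wherever `flux > 0`.
#' @param total_time_s Total simulated time; defaults to the end of the
#'   last event.
#' @param dose_per_flash,flash_s,period_s,count Periodic form: each flash
#'   delivers `dose_per_flash` umol m^-2 over `flash_s` seconds (flux =
#'   dose / duration), repeated `count` times every `period_s` seconds.
#' @return An object of class `flash_train` with an `events` data.frame
#'   and `total_time_s`.
#' @examples
#' flash_train(dose_per_flash = 2.3, flash_s = 1, period_s = 7.5, count = 40)
#' @export
flash_train <- function(events = NULL, total_time_s = NULL,
                        dose_per_flash = NULL, flash_s = NULL,
                        period_s = NULL, count = NULL) {
  if (is.null(events)) {
    stopifnot(!is.null(dose_per_flash), !is.null(flash_s),
              !is.null(period_s), !is.null(count))
    if (flash_s <= 0) stop("flash_s must be positive")
    if (flash_s >= period_s) stop("flash duration must be < period")
    if (dose_per_flash < 0) stop("dose_per_flash must be non-negative")
    events <- data.frame(start = (seq_len(count) - 1) * period_s,
                         duration = flash_s,
                         flux = dose_per_flash / flash_s)
    if (is.null(total_time_s)) total_time_s <- count * period_s
  } else {
    events <- as.data.frame(events)
    names(events) <- c("start", "duration", "flux")
    events <- events[order(events$start), , drop = FALSE]
    if (any(events$flux < 0)) stop("fluxes must be non-negative")
    if (any(events$duration <= 0 & events$flux > 0))
      stop("events with positive flux need positive duration")
    ends <- events$start + events$duration
    if (nrow(events) > 1 &&
        any(events$start[-1] < ends[-nrow(events)] - 1e-12))
      stop("invalid train: overlapping events")
    if (is.null(total_time_s)) total_time_s <- max(ends)
    if (total_time_s < max(ends)) stop("total_time_s truncates events")
  }
  structure(list(events = events, total_time_s = total_time_s),
            class = "flash_train")
}

# Flatten a train into contiguous constant-flux segments covering
# [0, total_time_s]: data.frame(t0, t1, flux).
.train_segments <- function(train) {
  ev <- train$events
  t <- 0; seg <- list()
  for (i in seq_len(nrow(ev))) {
    if (ev$start[i] > t + 1e-12)
      seg[[length(seg) + 1L]] <- c(t, ev$start[i], 0)
    t1 <- min(ev$start[i] + ev$duration[i], train$total_time_s)
    if (t1 > ev$start[i])
      seg[[length(seg) + 1L]] <- c(max(t, ev$start[i]), t1, ev$flux[i])
    t <- max(t, t1)
    if (t >= train$total_time_s) break
  }
  if (t < train$total_time_s)
    seg[[length(seg) + 1L]] <- c(t, train$total_time_s, 0)
  out <- do.call(rbind, seg)
  data.frame(t0 = out[, 1], t1 = out[, 2], flux = out[, 3])
}

#' Simulate the adduct-state fraction under an illumination train
#'
#' Piecewise-exponential propagation of the two-state model. Within a
#' constant-flux segment the fraction relaxes exponentially toward the
#' segment equilibrium `A_eq = k_f / (k_f + k_r)` at rate `k_app`; in
#' darkness it decays as `exp(-dt / r)`. Both propagators are exact, so
#' the result does not depend on `dt` beyond the output sampling grid.
#'
#' @param train A [flash_train()].
#' @param params A [photocycle_params()].
#' @param dt Output sampling interval in s (> 0).
#' @param A0 Initial adduct fraction; default 0 (dark-adapted).
#' @return An object of class `adduct_trace`: data.frame with columns
#'   `time_s` and `adduct_fraction`, with the parameters attached.
#' @examples
#' tr <- flash_train(dose_per_flash = 2.3, flash_s = 1, period_s = 7.5,
#'                   count = 40)
#' p <- photocycle_params(206, 13.7, 0.17)
#' max(simulate_adduct(tr, p, dt = 0.05)$adduct_fraction)  # ~0.025
#' @export
simulate_adduct <- function(train, params, dt = 0.05, A0 = 0) {
  stopifnot(inherits(train, "flash_train"),
            inherits(params, "photocycle_params"))
  if (dt <= 0) stop("dt must be positive")
  if (A0 < 0 || A0 > 1) stop("initial fraction must lie in [0, 1]")
  segs <- .train_segments(train)
  times <- seq(0, train$total_time_s, by = dt)
  frac <- numeric(length(times))
  A <- A0
  t_prev <- 0
  i_seg <- 1L
  propagate <- function(A, flux, delta) {
    if (delta <= 0) return(A)
    k <- forward_rate(flux, params)
    if (k$k_f == 0) return(A * exp(-delta / params$relaxation_s))
    A_eq <- k$k_f / k$k_app
    A_eq + (A - A_eq) * exp(-k$k_app * delta)
  }
  for (j in seq_along(times)) {
    t_target <- times[j]
    while (t_prev < t_target - 1e-12) {
      seg_end <- segs$t1[i_seg]
      t_next <- min(seg_end, t_target)
      A <- propagate(A, segs$flux[i_seg], t_next - t_prev)
      t_prev <- t_next
      if (t_prev >= seg_end - 1e-12 && i_seg < nrow(segs))
        i_seg <- i_seg + 1L
    }
    frac[j] <- A
  }
  structure(data.frame(time_s = times, adduct_fraction = frac),
            params = params, class = c("adduct_trace", "data.frame"))
}

#' Fine-step ODE oracle for the adduct simulator
#'
#' Integrates dA/dt = k_f(t) (1 - A) - A / r with a classic fixed-step
#' fourth-order Runge-Kutta scheme, stepping flux discontinuities exactly.
#' Intended as an independent cross-check of [simulate_adduct()] in tests,
#' not for routine use.
#'
#' @inheritParams simulate_adduct
#' @param dt Integration (and output) step in s.
#' @return An `adduct_trace` as for [simulate_adduct()].
#' @export
ode_oracle <- function(train, params, dt = 0.001, A0 = 0) {
  stopifnot(inherits(train, "flash_train"),
            inherits(params, "photocycle_params"))
  if (dt <= 0) stop("dt must be positive")
  segs <- .train_segments(train)
  k_r <- 1 / params$relaxation_s
  out_t <- list(); out_a <- list()
  A <- A0
  for (i in seq_len(nrow(segs))) {
    k_f <- segs$flux[i] / params$sensitivity
    f <- function(a) k_f * (1 - a) - k_r * a
    n <- max(1L, ceiling((segs$t1[i] - segs$t0[i]) / dt))
    h <- (segs$t1[i] - segs$t0[i]) / n
    tt <- numeric(n); aa <- numeric(n)
    for (s in seq_len(n)) {
      k1 <- f(A); k2 <- f(A + h / 2 * k1)
      k3 <- f(A + h / 2 * k2); k4 <- f(A + h * k3)
      A <- A + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tt[s] <- segs$t0[i] + s * h; aa[s] <- A
    }
    out_t[[i]] <- tt; out_a[[i]] <- aa
  }
  structure(data.frame(time_s = c(0, unlist(out_t)),
                       adduct_fraction = c(A0, unlist(out_a))),
            params = params, class = c("adduct_trace", "data.frame"))
}

#' Periodic steady state of the adduct fraction
#'
#' Closed-form fixed point of the per-cycle map for a periodic flash
#' train: the peak fraction reached at the end of each flash, the trough
#' just before the next flash, and the exact cycle-average fraction.
#'
#' @param dose_per_flash Photon dose per flash, umol m^-2.
#' @param flash_s Flash duration, s; must be < `period_s`.
#' @param period_s Flash period, s.
#' @param params A [photocycle_params()].
#' @return List with `peak`, `trough` and `mean` fractions.
#' @examples
#' periodic_steady_state(2.3, 1, 7.5, photocycle_params(206, 13.7, 0.17))
#' @export
periodic_steady_state <- function(dose_per_flash, flash_s, period_s, params) {
  stopifnot(inherits(params, "photocycle_params"))
  if (flash_s <= 0 || flash_s >= period_s)
    stop("invalid protocol: need 0 < flash_s < period_s")
  if (dose_per_flash < 0) stop("dose_per_flash must be non-negative")
  if (dose_per_flash == 0) return(list(peak = 0, trough = 0, mean = 0))
  flux <- dose_per_flash / flash_s
  k <- forward_rate(flux, params)
  A_eq <- k$k_f / k$k_app
  r <- params$relaxation_s
  dark_s <- period_s - flash_s
  g_lit <- exp(-k$k_app * flash_s)
  g_dark <- exp(-dark_s / r)
  peak <- A_eq * (1 - g_lit) / (1 - g_lit * g_dark)
  trough <- peak * g_dark
  # exact integral over one cycle starting at the trough
  int_lit <- A_eq * flash_s + (trough - A_eq) * (1 - g_lit) / k$k_app
  int_dark <- peak * r * (1 - g_dark)
  list(peak = peak, trough = trough, mean = (int_lit + int_dark) / period_s)
}

#' Longest flash period maintaining a target mean adduct fraction
#'
#' Finds, by monotone bisection on the period, the longest flash period
#' whose periodic steady-state mean adduct fraction still meets `target`.
#' Longer periods mean less light: this designs the minimal-exposure
#' protocol for a construct.
#'
#' @param params A [photocycle_params()].
#' @param dose_per_flash Photon dose per flash, umol m^-2 (> 0).
#' @param flash_s Flash duration, s.
#' @param target_mean_fraction Required mean adduct fraction in [0, 1).
#' @param max_period_s Upper bound of the search, s (default 1e6).
#' @param tol Relative bisection tolerance on the period.
#' @return Period in s; `Inf` when `target_mean_fraction` is 0 (no
#'   illumination needed). Errors when the target exceeds what continuous
#'   illumination at the flash flux can sustain.
#' @export
design_min_rate <- function(params, dose_per_flash, flash_s,
                            target_mean_fraction, max_period_s = 1e6,
                            tol = 1e-10) {
  stopifnot(inherits(params, "photocycle_params"))
  if (target_mean_fraction < 0 || target_mean_fraction >= 1)
    stop("target_mean_fraction must lie in [0, 1)")
  if (target_mean_fraction == 0) return(Inf)
  if (dose_per_flash <= 0) stop("dose_per_flash must be positive")
  flux <- dose_per_flash / flash_s
  ceiling_frac <- equilibrium_fraction(flux, params)
  if (target_mean_fraction >= ceiling_frac)
    stop(sprintf(paste0("infeasible target: mean fraction %.4g exceeds the ",
                        "continuous-light equilibrium %.4g at this flux"),
                 target_mean_fraction, ceiling_frac))
  mean_at <- function(P)
    periodic_steady_state(dose_per_flash, flash_s, P, params)$mean
  lo <- flash_s * (1 + 1e-9)
  if (mean_at(lo) < target_mean_fraction)
    stop("infeasible target: not achievable even at back-to-back flashes")
  hi <- max_period_s
  if (mean_at(hi) >= target_mean_fraction) return(hi)
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (mean_at(mid) >= target_mean_fraction) lo <- mid else hi <- mid
  }
  lo
}
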