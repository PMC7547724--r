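# CycleTraceSet: normalised fluorescence readings organised as activation
# cycles, each annotated with its preceding dark time and per-flash dose,
# plus matched LOV2-free control traces used for bleach correction.

#' Cycle-organised fluorescence trace set
#'
#' @param readings Data.frame with columns `sample_id`, `cycle_index`
#'   (1-based), `reading_index` (0-based within cycle) and `intensity_au`.
#' @param dark_times_s Dark time preceding each cycle, s; one value per
#'   cycle. The first dark period of a session, effectively infinite, is
#'   conventionally recorded as the 600 s sentinel.
#' @param dose_per_flash Photon dose per flash, umol m^-2.
#' @param flash_rate_hz Flash (= reading) rate, Hz; default 4.
#' @param control_readings Optional matched trace from a LOV2-free
#'   fluorophore sample under identical illumination; same columns.
#' @param normalized Whether intensities are already control-corrected
#'   and scaled to start at 1.
#' @return An object of class `cycle_trace_set`.
#' @export
cycle_trace_set <- function(readings, dark_times_s, dose_per_flash,
                            flash_rate_hz = 4, control_readings = NULL,
                            normalized = FALSE) {
  readings <- as.data.frame(readings)
  need <- c("sample_id", "cycle_index", "reading_index", "intensity_au")
  if (!all(need %in% names(readings)))
    stop("readings need columns: ", paste(need, collapse = ", "))
  n_cycles <- length(unique(readings$cycle_index))
  if (length(dark_times_s) != n_cycles)
    stop("dark_times_s must have one entry per cycle")
  per_cycle <- table(readings$cycle_index, readings$sample_id)
  if (any(per_cycle > 0 & per_cycle < 3))
    stop("every cycle needs at least 3 readings")
  if (!normalized && any(readings$intensity_au <= 0))
    stop("raw intensities must be positive")
  if (!is.null(control_readings)) {
    control_readings <- as.data.frame(control_readings)
    if (!all(need %in% names(control_readings)))
      stop("control_readings need columns: ", paste(need, collapse = ", "))
  }
  structure(list(readings = readings, dark_times_s = dark_times_s,
                 dose_per_flash = dose_per_flash,
                 flash_rate_hz = flash_rate_hz,
                 control_readings = control_readings,
                 normalized = normalized),
            class = "cycle_trace_set")
}

#' @export
print.cycle_trace_set <- function(x, ...) {
  cat(sprintf(paste0("<cycle_trace_set> %d samples, %d cycles, %d readings",
                     " (dose %g umol m^-2 per flash at %g Hz)%s%s\n"),
              length(unique(x$readings$sample_id)),
              length(x$dark_times_s), nrow(x$readings),
              x$dose_per_flash, x$flash_rate_hz,
              if (x$normalized) ", normalized" else "",
              if (is.null(x$control_readings)) "" else ", with control"))
  invisible(x)
}

#' Normalise traces to a matched LOV2-free control
#'
#' Divides every reading pointwise by the replicate-averaged control trace
#' (cancelling shared multiplicative photobleaching), then divides each
#' sample's trace by its first retained data point so it starts at 1.
#'
#' @param trace A [cycle_trace_set()] with `control_readings` present.
#' @return A normalised `cycle_trace_set` (control dropped, flag set).
#' @export
normalize_to_control <- function(trace) {
  stopifnot(inherits(trace, "cycle_trace_set"))
  if (is.null(trace$control_readings))
    stop("missing control: normalize_to_control needs control_readings")
  key <- function(d) paste(d$cycle_index, d$reading_index)
  ctrl <- stats::aggregate(intensity_au ~ cycle_index + reading_index,
                           data = trace$control_readings, FUN = mean)
  ctrl_map <- stats::setNames(ctrl$intensity_au, key(ctrl))
  if (any(ctrl_map == 0)) stop("degenerate control: zero control intensity")
  rd <- trace$readings
  cv <- ctrl_map[key(rd)]
  if (any(is.na(cv)))
    stop("protocol mismatch: control lacks readings present in trace")
  rd$intensity_au <- rd$intensity_au / cv
  # scale each sample to its first retained reading
  rd <- rd[order(rd$sample_id, rd$cycle_index, rd$reading_index), ]
  for (s in unique(rd$sample_id)) {
    i <- rd$sample_id == s
    rd$intensity_au[i] <- rd$intensity_au[i] / rd$intensity_au[i][1]
  }
  cycle_trace_set(rd, trace$dark_times_s, trace$dose_per_flash,
                  trace$flash_rate_hz, control_readings = NULL,
                  normalized = TRUE)
}

# average replicate samples per (cycle, reading); returns a data.frame
.average_replicates <- function(readings) {
  stats::aggregate(intensity_au ~ cycle_index + reading_index,
                   data = readings, FUN = mean)
}

#' Read a cycle trace CSV
#'
#' Expects the exact column set `sample_id, construct, is_control,
#' cycle_index, reading_index, dark_time_s, dose_per_flash_umol_m2,
#' flash_rate_hz, intensity_au`. Control rows are marked `is_control = 1`.
#'
#' @param path CSV path.
#' @return A [cycle_trace_set()] (unnormalised).
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "construct", "is_control", "cycle_index",
            "reading_index", "dark_time_s", "dose_per_flash_umol_m2",
            "flash_rate_hz", "intensity_au")
  if (!all(need %in% names(d)))
    stop("trace CSV needs columns: ", paste(need, collapse = ", "))
  ctl <- d[d$is_control == 1, ]
  smp <- d[d$is_control == 0, ]
  if (nrow(smp) == 0) stop("no non-control rows in trace CSV")
  dk <- unique(smp[, c("cycle_index", "dark_time_s")])
  dk <- dk[order(dk$cycle_index), ]
  cycle_trace_set(smp[, c("sample_id", "cycle_index", "reading_index",
                          "intensity_au")],
                  dark_times_s = dk$dark_time_s,
                  dose_per_flash = smp$dose_per_flash_umol_m2[1],
                  flash_rate_hz = smp$flash_rate_hz[1],
                  control_readings = if (nrow(ctl))
                    ctl[, c("sample_id", "cycle_index", "reading_index",
                            "intensity_au")] else NULL)
}

#' Write a cycle trace set to CSV
#'
#' @param trace A [cycle_trace_set()].
#' @param path Output path.
#' @param construct Construct label for the `construct` column.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, construct = "construct") {
  stopifnot(inherits(trace, "cycle_trace_set"))
  dk <- stats::setNames(trace$dark_times_s,
                        sort(unique(trace$readings$cycle_index)))
  row_of <- function(d, is_control) {
    data.frame(sample_id = d$sample_id, construct = construct,
               is_control = is_control, cycle_index = d$cycle_index,
               reading_index = d$reading_index,
               dark_time_s = dk[as.character(d$cycle_index)],
               dose_per_flash_umol_m2 = trace$dose_per_flash,
               flash_rate_hz = trace$flash_rate_hz,
               intensity_au = d$intensity_au)
  }
  out <- row_of(trace$readings, 0L)
  if (!is.null(trace$control_readings))
    out <- rbind(out, row_of(trace$control_readings, 1L))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialise photocycle parameters to JSON (unit-suffixed keys)
#'
#' @param params A [photocycle_params()].
#' @param path Optional output path; when NULL the JSON string is returned.
#' @return JSON string or `path`.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "photocycle_params"))
  x <- list(sensitivity_umol_m2 = params$sensitivity,
            relaxation_s = params$relaxation_s,
            transfer_limit_frac = params$transfer_limit,
            mode = params$mode)
  if (is.null(path))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read photocycle parameters from JSON
#'
#' @param path JSON file path or literal JSON string.
#' @return A [photocycle_params()].
#' @export
params_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  photocycle_params(as.numeric(x$sensitivity_umol_m2),
                    as.numeric(x$relaxation_s),
                    as.numeric(x$transfer_limit_frac), x$mode)
}

#' Read a flash train from JSON
#'
#' Accepts `{"periodic": {"dose_umol_m2": ..., "flash_s": ...,
#' "period_s": ..., "count": ...}}` or
#' `{"events": [[start, duration, flux], ...]}`.
#'
#' @param path JSON file path or literal JSON string.
#' @return A [flash_train()].
#' @export
train_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (!is.null(x$periodic)) {
    p <- x$periodic
    flash_train(dose_per_flash = p$dose_umol_m2, flash_s = p$flash_s,
                period_s = p$period_s, count = p$count)
  } else if (!is.null(x$events)) {
    flash_train(events = as.data.frame(x$events),
                total_time_s = x$total_time_s)
  } else stop("train JSON needs 'periodic' or 'events'")
}

#' Write a fit report to JSON
#'
#' @param fit A `fit_result`.
#' @param path Output path; when NULL the JSON string is returned.
#' @return JSON string or `path`.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  params <- lapply(seq_len(nrow(fit$params)), function(i)
    list(best_fit = fit$params$best_fit[i], se = fit$params$se[i]))
  names(params) <- rownames(fit$params)
  x <- list(model = fit$model, params = params, derived = fit$derived,
            ssr = fit$ssr, dof = fit$dof, converged = fit$converged,
            flags = fit$flags)
  if (is.null(path))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
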