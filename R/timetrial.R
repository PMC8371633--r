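# Time-trial processing: 1-Hz resampling, windowed summaries, and the
# aerobic/anaerobic decomposition of the required metabolic rate, whose
# time integral is the anaerobic capacity.

#' Construct/validate a 1-Hz time-trial series
#'
#' A time-trial record on a strictly increasing integer-second grid with
#' speed (m·s⁻¹), VO2 (mL·kg⁻¹·min⁻¹) and RER at each second. A 4-min TT
#' has t = 1..240; other durations are allowed with a warning.
#'
#' @param t Seconds from TT start (integer grid).
#' @param speed Speed, m·s⁻¹, non-negative.
#' @param vo2 Oxygen uptake, mL·kg⁻¹·min⁻¹.
#' @param rer Respiratory exchange ratio.
#' @param expected_duration Expected TT duration in s (default 240);
#'   deviations warn, they do not error.
#' @return A `data.frame` of class `tt_series`.
#' @export
tt_series <- function(t, speed, vo2, rer, expected_duration = 240) {
  stopifnot(length(t) == length(speed), length(t) == length(vo2),
            length(t) == length(rer))
  if (length(t) < 1) stop("empty time-trial series", call. = FALSE)
  if (any(t != round(t)) || any(diff(t) != 1)) {
    stop("tt_series requires a strictly increasing 1-s integer grid",
         call. = FALSE)
  }
  if (any(speed < 0, na.rm = TRUE)) {
    stop("negative speed in time-trial series", call. = FALSE)
  }
  if (length(t) != expected_duration) {
    warning("time-trial length ", length(t), " s differs from the expected ",
            expected_duration, " s")
  }
  structure(data.frame(t = t, speed = speed, vo2 = vo2, rer = rer),
            class = c("tt_series", "data.frame"))
}

#' Linearly resample irregular records to a 1-Hz grid
#'
#' Linear interpolation of every value column onto the integer-second grid
#' spanning the record (treadmill logs arrive at e.g. 2.46 Hz, gas exchange
#' at breath timing). No extrapolation: values outside the sampled range
#' hold the first/last sample constant.
#'
#' @param samples A `data.frame` with a time column and numeric value
#'   columns.
#' @param time_col Name of the time column (seconds).
#' @param grid Integer-second grid to interpolate onto; default
#'   `ceiling(min(t))..floor(max(t))`.
#' @return A `data.frame` on the 1-Hz grid; a `tt_series` when the columns
#'   `speed`, `vo2`, `rer` are all present.
#' @export
resample_to_1hz <- function(samples, time_col = "t", grid = NULL) {
  stopifnot(inherits(samples, "data.frame"), time_col %in% names(samples))
  tt <- samples[[time_col]]
  if (length(tt) < 2) {
    stop("at least two samples are required for interpolation",
         call. = FALSE)
  }
  if (is.unsorted(tt)) {
    stop("timestamps must be non-decreasing", call. = FALSE)
  }
  if (is.null(grid)) grid <- seq(ceiling(min(tt)), floor(max(tt)))
  vals <- setdiff(names(samples), time_col)
  out <- data.frame(t = grid)
  for (v in vals) {
    out[[v]] <- stats::approx(tt, samples[[v]], xout = grid, rule = 2,
                              ties = mean)$y
  }
  if (all(c("speed", "vo2", "rer") %in% names(out))) {
    out <- tt_series(out$t, out$speed, out$vo2, out$rer,
                     expected_duration = length(grid))
  }
  out
}

#' Average gas exchange over a submaximal stage window
#'
#' Arithmetic mean of VO2 and RER (and any other numeric columns) over the
#' steady-state window 2:50-3:50 of a 4-min stage (inclusive bounds),
#' i.e. seconds `stage_start + 170` to `stage_start + 230`.
#'
#' @param series A `data.frame` with columns `t`, `vo2`, `rer` (1-Hz).
#' @param stage_start Stage start time, s.
#' @param window Offsets (s) of the averaging window relative to
#'   `stage_start`; default `c(170, 230)`.
#' @return A list with the window means of every numeric column except `t`.
#' @export
stage_window_average <- function(series, stage_start, window = c(170, 230)) {
  lo <- stage_start + window[1]
  hi <- stage_start + window[2]
  sel <- series$t >= lo & series$t <= hi
  if (min(series$t) > lo || max(series$t) < hi) {
    stop("insufficient data: record does not cover the averaging window [",
         lo, ", ", hi, "] s", call. = FALSE)
  }
  cols <- setdiff(names(series)[vapply(series, is.numeric, logical(1))], "t")
  lapply(stats::setNames(cols, cols), function(v) mean(series[[v]][sel]))
}

#' Highest moving-window average
#'
#' Maximum over all contiguous window-length means of a 1-Hz series. Used
#' with `window = 30` for VO2peak and peak ventilation and `window = 5`
#' for peak heart rate.
#'
#' @param x Numeric 1-Hz series.
#' @param window Window length, s (samples).
#' @return The peak windowed mean.
#' @export
rolling_peak <- function(x, window) {
  n <- length(x)
  if (window < 1 || window != round(window)) {
    stop("window must be a positive integer", call. = FALSE)
  }
  if (n < window) {
    stop("series (", n, ") shorter than window (", window, ")",
         call. = FALSE)
  }
  cs <- cumsum(c(0, x))
  max((cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window)
}

#' Per-second aerobic metabolic rate of a time trial
#'
#' Applies the Weir-type conversion ([metabolic_rate()]) to the measured
#' VO2 and RER at each second, with RER clamped at 1.00 (seconds below
#' 1.00 use the measured RER).
#'
#' @param series A [tt_series()].
#' @return Numeric vector of aerobic MR, W·kg⁻¹, one value per second.
#' @export
aerobic_mr_series <- function(series) {
  stopifnot(inherits(series, "tt_series"))
  metabolic_rate(series$vo2, series$rer)
}

#' Per-second anaerobic metabolic rate
#'
#' Element-wise required minus aerobic MR. Negative seconds (aerobic supply
#' exceeding the modeled requirement) are retained: the integral is a net
#' oxygen-deficit.
#'
#' @param required,aerobic Equal-length per-second MR vectors, W·kg⁻¹.
#' @return Per-second anaerobic MR, W·kg⁻¹.
#' @export
anaerobic_mr_series <- function(required, aerobic) {
  if (length(required) != length(aerobic)) {
    stop("required and aerobic series differ in length", call. = FALSE)
  }
  required - aerobic
}

#' Integrate anaerobic metabolic rate to anaerobic capacity
#'
#' Rectangle-rule time integral of the 1-Hz anaerobic MR series
#' (dt = 1 s), in kJ·kg⁻¹.
#'
#' @param mr_an Per-second anaerobic MR, W·kg⁻¹.
#' @return Anaerobic capacity, kJ·kg⁻¹.
#' @export
integrate_anc <- function(mr_an) {
  if (length(mr_an) == 0) stop("empty series", call. = FALSE)
  sum(mr_an) / 1000
}

#' Anaerobic capacity of one time trial under one demand model
#'
#' The full per-participant computation: builds (or accepts) the demand
#' model, evaluates the required MR at every second's speed, subtracts the
#' measured aerobic MR, and integrates the anaerobic MR over the trial.
#'
#' @param stages A [stage_table()] of submaximal stages.
#' @param baseline A [baseline_summary()] (required by the `+Y` models).
#' @param tt A [tt_series()].
#' @param model A registry label (see [anc_models()]) or a fitted
#'   `speed_mr_model`.
#' @param vo2peak Optional VO2peak (mL·kg⁻¹·min⁻¹); default is the highest
#'   30-s moving average of the TT VO2 trace.
#' @param lag_shift Optional fixed time shift (s) applied to the
#'   gas-exchange columns before analysis (positive shifts VO2/RER
#'   earlier); default 0 (no mixing-chamber lag correction).
#' @return An `anc_result` list: `model_id`, `anc` (kJ·kg⁻¹), `o2_deficit`
#'   (mL·kg⁻¹), `mean_required_mr`, `mean_aerobic_mr` (W·kg⁻¹),
#'   `anaerobic_fraction` (%), `gec_tt_avg` (J·kg⁻¹·m⁻¹; the mean over
#'   seconds of required MR / speed, or the fixed model's GEC exactly),
#'   `mr_req_pct_peak` (% of peak aerobic MR), `distance` (m),
#'   `n_negative_seconds`, and an `extrapolated` flag with the fitted
#'   speed range.
#' @export
compute_anc <- function(stages, baseline, tt, model, vo2peak = NULL,
                        lag_shift = 0) {
  stopifnot(inherits(tt, "tt_series"))
  if (is.character(model)) {
    model <- demand_model(model, stages, baseline)
  }
  stopifnot(inherits(model, "speed_mr_model"))
  if (lag_shift != 0) {
    shifted <- resample_to_1hz(
      data.frame(t = tt$t - lag_shift, vo2 = tt$vo2, rer = tt$rer),
      grid = tt$t)
    tt$vo2 <- shifted$vo2
    tt$rer <- shifted$rer
  }
  req <- required_mr(model, tt$speed)
  ae <- aerobic_mr_series(tt)
  an <- anaerobic_mr_series(req, ae)
  anc <- integrate_anc(an)
  if (is.null(vo2peak)) vo2peak <- rolling_peak(tt$vo2, min(30, nrow(tt)))
  peak_mr <- peak_aerobic_mr(vo2peak)
  gec_tt <- if (model$form == "fixed_gec") {
    model$gec_value
  } else {
    ok <- tt$speed > 0
    mean(req[ok] / tt$speed[ok])
  }
  structure(list(
    model_id = model$label %||% model$form,
    anc = anc,
    o2_deficit = anc_to_o2_deficit(anc, units = "kJ"),
    mean_required_mr = mean(req),
    mean_aerobic_mr = mean(ae),
    anaerobic_fraction = 100 * (1 - mean(ae) / mean(req)),
    gec_tt_avg = gec_tt,
    mr_req_pct_peak = 100 * mean(req) / peak_mr,
    vo2peak = vo2peak,
    distance = sum(tt$speed),
    duration = nrow(tt),
    n_negative_seconds = sum(an < 0),
    extrapolated = max(tt$speed) > model$speed_range[2] ||
      min(tt$speed[tt$speed > 0]) < model$speed_range[1],
    model_speed_range = model$speed_range
  ), class = "anc_result")
}

#' @export
print.anc_result <- function(x, ...) {
  cat(sprintf("AnC [%s]: %.3f kJ/kg (O2 deficit %.1f mL/kg)\n",
              x$model_id, x$anc, x$o2_deficit))
  cat(sprintf("  required MR %.2f W/kg (%.0f%% of peak), aerobic %.2f W/kg, anaerobic fraction %.1f%%\n",
              x$mean_required_mr, x$mr_req_pct_peak, x$mean_aerobic_mr,
              x$anaerobic_fraction))
  cat(sprintf("  TT-average GEC %.2f J/kg/m over %d s (%.0f m)%s\n",
              x$gec_tt_avg, x$duration, x$distance,
              if (x$extrapolated) " [extrapolated beyond fitted speeds]"
              else ""))
  invisible(x)
}

#' @export
as.data.frame.anc_result <- function(x, ...) {
  data.frame(
    model_id = x$model_id,
    anc = x$anc,
    o2_deficit = x$o2_deficit,
    mean_required_mr = x$mean_required_mr,
    mean_aerobic_mr = x$mean_aerobic_mr,
    anaerobic_fraction = x$anaerobic_fraction,
    gec_tt_avg = x$gec_tt_avg,
    mr_req_pct_peak = x$mr_req_pct_peak,
    vo2peak = x$vo2peak,
    distance = x$distance,
    duration = x$duration,
    n_negative_seconds = x$n_negative_seconds,
    extrapolated = x$extrapolated,
    stringsAsFactors = FALSE
  )
}
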