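# Gas-exchange -> energy conversions. Unit contract, package-wide:
# VO2 in mL.kg-1.min-1, metabolic rate (MR) in W.kg-1, speed in m.s-1,
# energy cost in J.kg-1.m-1, anaerobic capacity reported in kJ.kg-1
# (internally J.kg-1). km.h-1 is accepted at the I/O boundary only.

# mL of O2 per joule of anaerobic energy at 100% carbohydrate utilization
O2_ML_PER_JOULE <- 0.047801

# Physiological plausibility gate for the respiratory exchange ratio
RER_BOUNDS <- c(0.6, 1.4)

#' Metabolic rate from oxygen uptake and RER
#'
#' Converts oxygen uptake and the respiratory exchange ratio (RER) into a
#' whole-body metabolic rate with the Weir-type energy equivalent
#' \deqn{MR = 4.184 \cdot \dot{V}O_2 (1.1\,RER + 3.9) / 60}{
#'       MR = 4.184 * VO2 * (1.1 * RER + 3.9) / 60}
#' where the RER term indexes the substrate mix. RER values above 1.00
#' (excess non-metabolic CO2 during heavy exercise) are clamped to 1.00
#' before use, so the energy equivalent never exceeds the 100% carbohydrate
#' value.
#'
#' @param vo2 Oxygen uptake, mL·kg⁻¹·min⁻¹. Must be non-negative.
#' @param rer Respiratory exchange ratio (VCO2/VO2), dimensionless. Values
#'   outside \[0.6, 1.4\] are rejected as sensor error; values in
#'   (1.00, 1.4\] are clamped to 1.00.
#' @return Metabolic rate, W·kg⁻¹. Vectorized over both arguments.
#' @examples
#' metabolic_rate(58, 1.00)   # 20.22 W/kg
#' metabolic_rate(33.72, 0.90)
#' @export
metabolic_rate <- function(vo2, rer) {
  stopifnot(is.numeric(vo2), is.numeric(rer))
  if (any(vo2 < 0, na.rm = TRUE)) {
    stop("negative oxygen uptake: vo2 = ",
         paste(signif(vo2[which(vo2 < 0)], 4), collapse = ", "),
         " mL.kg-1.min-1", call. = FALSE)
  }
  bad <- rer < RER_BOUNDS[1] | rer > RER_BOUNDS[2]
  if (any(bad, na.rm = TRUE)) {
    stop("RER outside the plausibility gate [", RER_BOUNDS[1], ", ",
         RER_BOUNDS[2], "]: ",
         paste(signif(rer[which(bad)], 4), collapse = ", "), call. = FALSE)
  }
  4.184 * vo2 * (1.1 * pmin(rer, 1.00) + 3.9) / 60
}

#' Oxygen uptake implied by a metabolic rate
#'
#' Inverts [metabolic_rate()] at a given RER. Used by the synthetic-data
#' generator to turn a true metabolic rate into an observable VO2 trace.
#'
#' @param mr Metabolic rate, W·kg⁻¹.
#' @param rer Respiratory exchange ratio; clamped at 1.00 like the forward
#'   conversion.
#' @return Oxygen uptake, mL·kg⁻¹·min⁻¹.
#' @export
vo2_from_mr <- function(mr, rer) {
  stopifnot(is.numeric(mr), is.numeric(rer))
  bad <- rer < RER_BOUNDS[1] | rer > RER_BOUNDS[2]
  if (any(bad, na.rm = TRUE)) {
    stop("RER outside the plausibility gate [", RER_BOUNDS[1], ", ",
         RER_BOUNDS[2], "]", call. = FALSE)
  }
  mr * 60 / (4.184 * (1.1 * pmin(rer, 1.00) + 3.9))
}

#' Gross energy cost of running
#'
#' Energy required per kilogram of body mass per metre of locomotion:
#' metabolic rate divided by speed.
#'
#' @param mr Metabolic rate, W·kg⁻¹.
#' @param speed Treadmill speed, m·s⁻¹. Must be strictly positive.
#' @return Gross energy cost, J·kg⁻¹·m⁻¹.
#' @examples
#' gross_energy_cost(11.5, 2.60)  # 4.42 J/kg/m
#' @export
gross_energy_cost <- function(mr, speed) {
  stopifnot(is.numeric(mr), is.numeric(speed))
  if (any(speed <= 0, na.rm = TRUE)) {
    stop("energy cost is undefined at speed <= 0 m.s-1", call. = FALSE)
  }
  mr / speed
}

#' Net energy cost of running
#'
#' Gross energy cost with the standing-baseline metabolic rate removed
#' before dividing by speed: (MR - MR_BL) / speed.
#'
#' @inheritParams gross_energy_cost
#' @param mr_bl Standing baseline metabolic rate, W·kg⁻¹.
#' @return Net energy cost, J·kg⁻¹·m⁻¹.
#' @export
net_energy_cost <- function(mr, mr_bl, speed) {
  stopifnot(is.numeric(mr_bl))
  gross_energy_cost(mr - mr_bl, speed)
}

#' Peak aerobic metabolic rate
#'
#' Converts VO2peak to a peak aerobic metabolic rate assuming 100%
#' carbohydrate utilization (RER = 1.00).
#'
#' @param vo2peak Peak oxygen uptake, mL·kg⁻¹·min⁻¹.
#' @return Peak aerobic metabolic rate, W·kg⁻¹.
#' @export
peak_aerobic_mr <- function(vo2peak) {
  if (any(vo2peak < 0, na.rm = TRUE)) {
    stop("vo2peak must be non-negative", call. = FALSE)
  }
  metabolic_rate(vo2peak, 1.00)
}

#' Accumulated oxygen deficit from anaerobic energy
#'
#' Converts anaerobic energy to an oxygen-equivalent accumulated deficit
#' using 0.047801 mL O2 per joule (100% carbohydrate utilization). Negative
#' input (net aerobic surplus) is allowed and flagged with a warning.
#'
#' @param anc Anaerobic energy, J·kg⁻¹ (default) or kJ·kg⁻¹.
#' @param units Units of `anc`: `"J"` or `"kJ"`.
#' @return Accumulated oxygen deficit, mL·kg⁻¹.
#' @examples
#' anc_to_o2_deficit(540)           # 25.81 mL/kg
#' anc_to_o2_deficit(0.54, "kJ")
#' @export
anc_to_o2_deficit <- function(anc, units = c("J", "kJ")) {
  units <- match.arg(units)
  if (units == "kJ") anc <- anc * 1000
  if (any(anc < 0, na.rm = TRUE)) {
    warning("negative anaerobic energy converted to a negative O2 deficit")
  }
  anc * O2_ML_PER_JOULE
}

#' Assemble a submaximal stage table
#'
#' Builds the per-stage summary used by the demand-model fits. Each row is
#' one submaximal stage with its averaged physiology; metabolic rate and
#' gross energy cost are derived on construction. Exactly one of
#' (`vo2` + `rer`), `mr`, or `gec` must supply the energy information:
#' gas exchange is converted with [metabolic_rate()], a given `gec` implies
#' `mr = gec * speed`.
#'
#' @param speed Stage speeds, m·s⁻¹ (see `speed_unit`). Strictly positive.
#' @param vo2,rer Stage-average gas exchange (optional if `mr`/`gec` given).
#' @param mr Stage metabolic rates, W·kg⁻¹ (optional).
#' @param gec Measured gross energy costs, J·kg⁻¹·m⁻¹ (optional).
#' @param hr,lactate,rpe Carried annotations (heart rate, blood lactate,
#'   rating of perceived exertion); not used in any computation.
#' @param speed_unit `"m/s"` (default) or `"km/h"`; km/h is converted on
#'   ingest.
#' @return A `data.frame` of class `stage_table`, sorted by speed, with
#'   columns `speed`, `vo2`, `rer`, `mr`, `gec` plus carried annotations.
#' @export
stage_table <- function(speed, vo2 = NULL, rer = NULL, mr = NULL, gec = NULL,
                        hr = NULL, lactate = NULL, rpe = NULL,
                        speed_unit = c("m/s", "km/h")) {
  speed_unit <- match.arg(speed_unit)
  if (speed_unit == "km/h") speed <- speed / 3.6
  if (any(!is.finite(speed)) || any(speed <= 0)) {
    stop("stage speeds must be finite and > 0", call. = FALSE)
  }
  n <- length(speed)
  if (!is.null(mr)) {
    stopifnot(length(mr) == n)
  } else if (!is.null(gec)) {
    stopifnot(length(gec) == n)
    mr <- gec * speed
  } else if (!is.null(vo2) && !is.null(rer)) {
    stopifnot(length(vo2) == n, length(rer) == n)
    mr <- metabolic_rate(vo2, rer)
  } else {
    stop("supply vo2 + rer, or mr, or gec", call. = FALSE)
  }
  if (is.null(gec)) gec <- gross_energy_cost(mr, speed)
  out <- data.frame(
    speed = speed,
    vo2 = if (is.null(vo2)) NA_real_ else vo2,
    rer = if (is.null(rer)) NA_real_ else rer,
    mr = mr,
    gec = gec,
    hr = if (is.null(hr)) NA_real_ else hr,
    lactate = if (is.null(lactate)) NA_real_ else lactate,
    rpe = if (is.null(rpe)) NA_real_ else rpe
  )
  out <- out[order(out$speed), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stage_table", "data.frame")
  out
}

#' Standing baseline summary
#'
#' The resting (standing) gas-exchange summary whose metabolic rate anchors
#' the 5+Y regression models at zero speed and the net-energy-cost
#' calculation.
#'
#' @param vo2,rer Baseline gas exchange (optional if `mr_bl` given).
#' @param mr_bl Baseline metabolic rate, W·kg⁻¹ (optional; derived from
#'   `vo2`/`rer` otherwise).
#' @return A list of class `baseline_summary` with elements `vo2`, `rer`,
#'   `mr_bl`.
#' @export
baseline_summary <- function(vo2 = NULL, rer = NULL, mr_bl = NULL) {
  if (is.null(mr_bl)) {
    if (is.null(vo2) || is.null(rer)) {
      stop("supply vo2 + rer, or mr_bl", call. = FALSE)
    }
    mr_bl <- metabolic_rate(vo2, rer)
  }
  if (!is.finite(mr_bl) || mr_bl < 0) {
    stop("baseline metabolic rate must be finite and >= 0", call. = FALSE)
  }
  structure(list(vo2 = vo2 %||% NA_real_, rer = rer %||% NA_real_,
                 mr_bl = mr_bl),
            class = "baseline_summary")
}

#' @export
print.baseline_summary <- function(x, ...) {
  cat(sprintf("Standing baseline: MR = %.2f W/kg (VO2 %s, RER %s)\n",
              x$mr_bl,
              if (is.na(x$vo2)) "-" else sprintf("%.1f", x$vo2),
              if (is.na(x$rer)) "-" else sprintf("%.2f", x$rer)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Report-table rounding convention: two decimals for energy costs and
# model coefficients, integers for percentages and O2 deficits. Full
# precision is retained internally everywhere.
round_report <- function(x, what = c("gec", "percent", "o2", "coef")) {
  what <- match.arg(what)
  switch(what,
         gec = round(x, 2),
         coef = round(x, 2),
         percent = round(x),
         o2 = round(x))
}
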