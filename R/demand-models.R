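# Speed -> metabolic-rate demand models. Two families:
#   * regression models (linear or quadratic in speed), fitted to the
#     submaximal stages by OLS, optionally with the standing-baseline MR
#     appended as one extra, equally weighted observation at speed 0
#     ("+Y" models; the intercept is modeled, never forced);
#   * fixed gross-energy-cost models, where required MR = GEC * speed.

#' Registered demand-model labels
#'
#' The nine demand models: the four primary models (`5+Y_LIN`, `5-Y_LIN`,
#' `GEC_AVG`, `GEC_LAST`) and five supplementary models (`5+Y_POL`,
#' `5-Y_POL` second-degree polynomials; `4-Y_LIN`, `3-Y_LIN`, `2-Y_LIN`
#' reduced-stage linear fits on the highest-speed stages, baseline
#' excluded).
#'
#' @param primary_only If `TRUE`, return only the four primary models.
#' @return Character vector of model labels.
#' @export
anc_models <- function(primary_only = FALSE) {
  primary <- c("5+Y_LIN", "5-Y_LIN", "GEC_AVG", "GEC_LAST")
  if (primary_only) return(primary)
  c(primary, "5+Y_POL", "5-Y_POL", "4-Y_LIN", "3-Y_LIN", "2-Y_LIN")
}

new_speed_mr_model <- function(form, coefficients = NULL, gec_value = NULL,
                               include_baseline = FALSE, n_stages_used,
                               r2 = NA_real_, see = NA_real_,
                               speed_range = NULL, gec_source = NULL,
                               label = NULL) {
  structure(list(
    form = form,
    include_baseline = include_baseline,
    coefficients = coefficients,
    gec_value = gec_value,
    n_stages_used = n_stages_used,
    r2 = r2,
    see = see,
    speed_range = speed_range,
    gec_source = gec_source,
    label = label
  ), class = "speed_mr_model")
}

select_highest_stages <- function(stages, n_highest_stages) {
  n <- nrow(stages)
  if (n_highest_stages < 1 || n_highest_stages > n) {
    stop("n_highest_stages must be between 1 and the number of stages (",
         n, ")", call. = FALSE)
  }
  # stage_table is sorted by speed on construction; enforce anyway
  stages <- stages[order(stages$speed), , drop = FALSE]
  stages[seq(n - n_highest_stages + 1, n), , drop = FALSE]
}

#' Select submaximal stages by target intensity band
#'
#' When more than five stages were completed, keeps the `n` stages closest
#' to the 55-80% band of peak aerobic metabolic rate (distance zero inside
#' the band), breaking ties toward the higher intensity.
#'
#' @param stages A [stage_table()].
#' @param peak_mr Peak aerobic metabolic rate, W·kg⁻¹.
#' @param n Number of stages to keep (default 5).
#' @param band Target intensity band as fractions of `peak_mr`.
#' @return The selected rows of `stages`, sorted by speed.
#' @export
select_stages_by_intensity <- function(stages, peak_mr, n = 5,
                                       band = c(0.55, 0.80)) {
  if (nrow(stages) <= n) return(stages)
  frac <- stages$mr / peak_mr
  dist <- pmax(band[1] - frac, frac - band[2], 0)
  # ties toward higher intensity: sort by (distance, -frac)
  keep <- order(dist, -frac)[seq_len(n)]
  out <- stages[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a speed-metabolic-rate regression demand model
#'
#' Ordinary least squares of stage metabolic rate on stage speed, linear or
#' quadratic (raw, non-centered speed). With `include_baseline = TRUE` the
#' pair (0, MR_BL) is appended as one additional equally weighted
#' observation, so the Y-intercept is modeled from all points, not forced
#' to the baseline value.
#'
#' @param stages A [stage_table()]. Stages are used sorted by speed.
#' @param baseline A [baseline_summary()]; required when
#'   `include_baseline = TRUE`.
#' @param include_baseline Append the baseline point at speed 0?
#' @param form `"linear"` or `"quadratic"`.
#' @param n_highest_stages Use only the `n` highest-speed stages (default:
#'   all). The reduced-stage models use 4, 3 or 2.
#' @return A `speed_mr_model` with coefficients (W·kg⁻¹ and W·kg⁻¹ per
#'   m·s⁻¹), r², standard error of estimate `see` = sqrt(SSE/(n - p))
#'   (NA when the fit is exact with zero residual df), the number of stage
#'   observations used, and the fitted speed range (extrapolation beyond it
#'   is the method, but is flagged downstream).
#' @export
fit_speed_mr <- function(stages, baseline = NULL, include_baseline = FALSE,
                         form = c("linear", "quadratic"),
                         n_highest_stages = NULL) {
  form <- match.arg(form)
  stopifnot(inherits(stages, "data.frame"))
  if (is.null(n_highest_stages)) n_highest_stages <- nrow(stages)
  used <- select_highest_stages(stages, n_highest_stages)
  x <- used$speed
  y <- used$mr
  if (include_baseline) {
    if (is.null(baseline)) {
      stop("include_baseline = TRUE requires a baseline_summary",
           call. = FALSE)
    }
    x <- c(0, x)
    y <- c(baseline$mr_bl, y)
  }
  p <- if (form == "linear") 2L else 3L
  if (length(x) < p) {
    stop("underdetermined fit: ", length(x), " observations for ", p,
         " coefficients", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("singular fit: no variance in speed", call. = FALSE)
  }
  fit <- if (form == "linear") {
    stats::lm(y ~ x)
  } else {
    cn <- kappa(cbind(1, x, x^2), exact = TRUE)
    if (cn > 1e8) {
      warning("ill-conditioned quadratic design matrix (condition number ",
              format(cn, digits = 3), ")")
    }
    stats::lm(y ~ x + I(x^2))
  }
  cf <- unname(stats::coef(fit))
  names(cf) <- c("intercept", "slope", "quadratic")[seq_along(cf)]
  res <- stats::residuals(fit)
  sse <- sum(res^2)
  df_res <- length(x) - p
  exact <- df_res == 0 || sse < 1e-20 * max(1, sum(y^2))
  r2 <- if (exact) 1 else summary(fit)$r.squared
  see <- if (df_res == 0) NA_real_ else sqrt(sse / df_res)
  new_speed_mr_model(
    form = form, coefficients = cf,
    include_baseline = include_baseline,
    n_stages_used = nrow(used),
    r2 = r2, see = see,
    speed_range = range(used$speed)
  )
}

#' Fixed gross-energy-cost demand model
#'
#' A demand model that assumes a speed-independent gross energy cost, so
#' required MR = GEC × speed (zero intercept by construction). The GEC is
#' either the arithmetic mean of the per-stage measured GECs (`"avg"`) or
#' the GEC of the highest-speed stage (`"last"`).
#'
#' @param stages A [stage_table()] with at least one stage.
#' @param source `"avg"` or `"last"`.
#' @return A `speed_mr_model` with `form = "fixed_gec"`.
#' @export
fixed_gec_model <- function(stages, source = c("avg", "last")) {
  source <- match.arg(source)
  stopifnot(inherits(stages, "data.frame"))
  if (nrow(stages) < 1) stop("empty stage list", call. = FALSE)
  stages <- stages[order(stages$speed), , drop = FALSE]
  g <- if (source == "avg") mean(stages$gec) else stages$gec[nrow(stages)]
  new_speed_mr_model(
    form = "fixed_gec", gec_value = g,
    n_stages_used = if (source == "avg") nrow(stages) else 1L,
    gec_source = source,
    speed_range = range(stages$speed)
  )
}

#' Build a demand model from its registry label
#'
#' Maps one of the labels in [anc_models()] to its fitted/constructed
#' `speed_mr_model`: `k+Y`/`k-Y` regression models include/exclude the
#' baseline point, `LIN`/`POL` select linear or quadratic form, the leading
#' digit selects the number of highest-speed stages, and `GEC_AVG` /
#' `GEC_LAST` are the fixed-cost models. Reduced-stage models (`4-Y_LIN`,
#' `3-Y_LIN`, `2-Y_LIN`) exclude the baseline.
#'
#' @param label A model label, e.g. `"5+Y_LIN"`.
#' @inheritParams fit_speed_mr
#' @return A `speed_mr_model` carrying `label`.
#' @export
demand_model <- function(label, stages, baseline = NULL) {
  if (!label %in% anc_models()) {
    stop("unknown demand model '", label, "'; registered models: ",
         paste(anc_models(), collapse = ", "), call. = FALSE)
  }
  m <- if (label == "GEC_AVG") {
    fixed_gec_model(stages, "avg")
  } else if (label == "GEC_LAST") {
    fixed_gec_model(stages, "last")
  } else {
    n_st <- as.integer(substr(label, 1, 1))
    incl <- substr(label, 2, 2) == "+"
    form <- if (endsWith(label, "POL")) "quadratic" else "linear"
    fit_speed_mr(stages, baseline = baseline, include_baseline = incl,
                 form = form, n_highest_stages = n_st)
  }
  m$label <- label
  m
}

#' Required metabolic rate at a speed
#'
#' Evaluates a demand model: regression forms evaluate their polynomial in
#' speed, fixed-GEC models return `gec_value * speed`.
#'
#' @param model A `speed_mr_model`.
#' @param speed Speed(s), m·s⁻¹, non-negative.
#' @return Required metabolic rate, W·kg⁻¹ (vectorized).
#' @export
required_mr <- function(model, speed) {
  stopifnot(inherits(model, "speed_mr_model"))
  if (any(speed < 0, na.rm = TRUE)) {
    stop("speed must be non-negative", call. = FALSE)
  }
  if (model$form == "fixed_gec") return(model$gec_value * speed)
  cf <- model$coefficients
  out <- cf[["intercept"]] + cf[["slope"]] * speed
  if (model$form == "quadratic") out <- out + cf[["quadratic"]] * speed^2
  out
}

#' Gross energy cost implied by a demand model
#'
#' Required MR divided by speed. For regression models with a positive
#' intercept this decreases with speed (the diminishing relative
#' contribution of the intercept); fixed-GEC models return their constant.
#'
#' @inheritParams required_mr
#' @param speed Speed(s), m·s⁻¹, strictly positive.
#' @return Gross energy cost, J·kg⁻¹·m⁻¹.
#' @export
gec_from_model <- function(model, speed) {
  if (any(speed <= 0, na.rm = TRUE)) {
    stop("model GEC is undefined at speed <= 0", call. = FALSE)
  }
  if (model$form == "fixed_gec") return(rep(model$gec_value, length(speed)))
  required_mr(model, speed) / speed
}

#' Percentage RMSE of model GEC against measured stage GEC
#'
#' Root mean square, over the stages, of the relative (percent) error
#' between the model-implied GEC at each stage speed and the measured GEC.
#' Quantifies how well a demand model reproduces the measured submaximal
#' energy cost.
#'
#' @param model A `speed_mr_model`.
#' @param stages A [stage_table()] with measured `gec`.
#' @return RMSE, percent.
#' @export
rmse_percent_gec <- function(model, stages) {
  if (nrow(stages) < 1) stop("empty stage list", call. = FALSE)
  rel <- 100 * (gec_from_model(model, stages$speed) - stages$gec) /
    stages$gec
  sqrt(mean(rel^2))
}

#' @export
print.speed_mr_model <- function(x, ...) {
  lab <- if (is.null(x$label)) x$form else x$label
  if (x$form == "fixed_gec") {
    cat(sprintf("Demand model %s: fixed GEC = %.3f J/kg/m (%s of %d stage%s)\n",
                lab, x$gec_value, x$gec_source, x$n_stages_used,
                if (x$n_stages_used == 1) "" else "s"))
  } else {
    cf <- x$coefficients
    eq <- sprintf("MR = %.3f + %.3f*v", cf[["intercept"]], cf[["slope"]])
    if (x$form == "quadratic") {
      eq <- paste0(eq, sprintf(" + %.3f*v^2", cf[["quadratic"]]))
    }
    cat(sprintf("Demand model %s: %s (%s, %d stages%s)\n", lab, eq, x$form,
                x$n_stages_used,
                if (x$include_baseline) " + baseline point" else ""))
    cat(sprintf("  r2 = %.4f, SEE = %s W/kg, fitted speeds %.2f-%.2f m/s\n",
                x$r2, if (is.na(x$see)) "NA" else sprintf("%.3f", x$see),
                x$speed_range[1], x$speed_range[2]))
  }
  invisible(x)
}

#' Serialize a demand model to JSON
#'
#' @param model A `speed_mr_model`.
#' @return A JSON string with form, flags, coefficients and diagnostics.
#' @export
model_to_json <- function(model) {
  stopifnot(inherits(model, "speed_mr_model"))
  obj <- unclass(model)
  if (!is.null(obj$coefficients)) obj$coefficients <- as.list(obj$coefficients)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                   null = "null", na = "null")
}
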