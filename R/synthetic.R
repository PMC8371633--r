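# Synthetic participants with known true anaerobic capacity. The generator
# emulates the study cohort: five 4-min submaximal stages at ~55-80% of
# peak aerobic MR, a standing baseline, and a speed-controlled 4-min time
# trial whose VO2 follows mono-exponential on-kinetics toward the
# instantaneous demand ceiling.

# treadmill speed-controller limits, km/h per s, converted to m/s per s
TT_ACCEL_LIMIT <- 0.50 / 3.6
TT_DECEL_LIMIT <- 0.40 / 3.6

#' Ground-truth parameters for one synthetic participant
#'
#' The truth is a demand model plus aerobic kinetics. Exactly one demand
#' parameterization is active:
#' * linear metabolic rate (`demand_intercept` set): MR(v) = b + s·v with
#'   slope s chosen so that the gross energy cost at the reference speed
#'   `v_ref` equals `gec0`;
#' * speed-dependent gross energy cost (`gec_speed_slope` set, may be 0):
#'   GEC(v) = gec0 + slope·(v - v_ref), MR(v) = GEC(v)·v.
#'
#' The standing baseline MR is a separate parameter from the demand-line
#' intercept: standing still is not running, and the gap between the two is
#' exactly what biases demand models that anchor the regression at zero
#' speed.
#'
#' @param vo2peak Peak oxygen uptake, mL·kg⁻¹·min⁻¹.
#' @param baseline_mr Standing baseline MR, W·kg⁻¹.
#' @param gec0 Gross energy cost at the reference speed, J·kg⁻¹·m⁻¹.
#' @param v_ref Reference speed for `gec0`, m·s⁻¹ (default 3.13, the
#'   mid-submaximal speed).
#' @param demand_intercept Linear-MR truth intercept, W·kg⁻¹ (default 0.2
#'   when neither parameterization is specified).
#' @param gec_speed_slope GEC-truth slope, J·kg⁻¹·m⁻¹ per m·s⁻¹ (0 gives a
#'   speed-independent cost).
#' @param tau_on VO2 on-kinetics time constant, s.
#' @param rer_start,rer_end Stage RER, interpolated across stages.
#' @param rer_standing Standing baseline RER.
#' @param rer_tt Time-trial RER (1.00: 100% carbohydrate when
#'   supramaximal).
#' @param noise_sd_vo2 Additive Gaussian VO2 noise SD, mL·kg⁻¹·min⁻¹.
#' @return A list of class `truth_params`.
#' @export
truth_params <- function(vo2peak = 58, baseline_mr = 1.8, gec0 = 4.39,
                         v_ref = 3.13, demand_intercept = NULL,
                         gec_speed_slope = NULL, tau_on = 25,
                         rer_start = 0.90, rer_end = 0.95,
                         rer_standing = 0.88, rer_tt = 1.00,
                         noise_sd_vo2 = 0.45) {
  if (!is.null(demand_intercept) && !is.null(gec_speed_slope)) {
    stop("specify exactly one of demand_intercept or gec_speed_slope",
         call. = FALSE)
  }
  if (is.null(demand_intercept) && is.null(gec_speed_slope)) {
    demand_intercept <- 0.2
  }
  stopifnot(vo2peak > 0, baseline_mr >= 0, gec0 > 0, v_ref > 0, tau_on > 0,
            noise_sd_vo2 >= 0)
  tr <- list(vo2peak = vo2peak, baseline_mr = baseline_mr, gec0 = gec0,
             v_ref = v_ref, demand_intercept = demand_intercept,
             gec_speed_slope = gec_speed_slope, tau_on = tau_on,
             rer_start = rer_start, rer_end = rer_end,
             rer_standing = rer_standing, rer_tt = rer_tt,
             noise_sd_vo2 = noise_sd_vo2)
  if (!is.null(demand_intercept)) {
    tr$demand_slope <- gec0 - demand_intercept / v_ref
    if (tr$demand_slope <= 0) {
      stop("demand_intercept too large: implied slope is not positive",
           call. = FALSE)
    }
  }
  structure(tr, class = "truth_params")
}

#' True demand metabolic rate at a speed
#'
#' Evaluates the active truth parameterization of a [truth_params()].
#'
#' @param truth A `truth_params`.
#' @param speed Speed(s), m·s⁻¹.
#' @return True required MR, W·kg⁻¹.
#' @export
true_demand_mr <- function(truth, speed) {
  stopifnot(inherits(truth, "truth_params"))
  if (!is.null(truth$demand_intercept)) {
    truth$demand_intercept + truth$demand_slope * speed
  } else {
    (truth$gec0 + truth$gec_speed_slope * (speed - truth$v_ref)) * speed
  }
}

# invert the truth demand for the speed hitting a target MR
speed_for_demand <- function(truth, target) {
  if (!is.null(truth$demand_intercept)) {
    (target - truth$demand_intercept) / truth$demand_slope
  } else {
    g1 <- truth$gec_speed_slope
    b <- truth$gec0 - g1 * truth$v_ref
    if (g1 == 0) {
      target / b
    } else {
      # g1 v^2 + b v - target = 0, positive root
      (-b + sqrt(b^2 + 4 * g1 * target)) / (2 * g1)
    }
  }
}

#' Simulate the submaximal protocol for one participant
#'
#' Five (by default) stages spanning ~55-80% of peak aerobic MR: the stage
#' speeds are solved from the truth demand at the target intensity
#' fractions, stage RER is interpolated from `rer_start` to `rer_end`,
#' VO2 is the inversion of the Weir-type equation at the stage's true MR
#' plus additive Gaussian noise, and the standing baseline is generated
#' the same way from `baseline_mr`. Heart rate, lactate and RPE are
#' carried as plausible annotations only.
#'
#' @param truth A [truth_params()].
#' @param speeds Optional explicit stage speeds, m·s⁻¹ (increasing);
#'   default derived from `fractions`.
#' @param fractions Target stage intensities as fractions of peak aerobic
#'   MR (default 0.57 to 0.79, five stages).
#' @return A list with `stages` (a [stage_table()]) and `baseline`
#'   (a [baseline_summary()]). Uses the current RNG state.
#' @export
simulate_submax <- function(truth, speeds = NULL,
                            fractions = seq(0.57, 0.79, length.out = 5)) {
  stopifnot(inherits(truth, "truth_params"))
  peak <- peak_aerobic_mr(truth$vo2peak)
  if (is.null(speeds)) {
    speeds <- vapply(fractions * peak, function(m) speed_for_demand(truth, m),
                     numeric(1))
  }
  if (any(diff(speeds) <= 0)) {
    stop("stage speeds must be increasing", call. = FALSE)
  }
  n <- length(speeds)
  mr_true <- true_demand_mr(truth, speeds)
  if (any(mr_true > peak)) {
    stop("configuration error: a submaximal stage demand exceeds the peak ",
         "aerobic MR implied by vo2peak", call. = FALSE)
  }
  rer <- seq(truth$rer_start, truth$rer_end, length.out = n)
  vo2 <- pmax(0, vo2_from_mr(mr_true, rer) +
                stats::rnorm(n, 0, truth$noise_sd_vo2))
  frac <- mr_true / peak
  stages <- stage_table(
    speed = speeds, vo2 = vo2, rer = rer,
    hr = round(110 + 90 * frac),
    lactate = round(0.6 + 2 * frac^2, 1),
    rpe = round(6 + 12 * frac)
  )
  vo2_bl <- pmax(0, vo2_from_mr(truth$baseline_mr, truth$rer_standing) +
                   stats::rnorm(1, 0, truth$noise_sd_vo2))
  list(stages = stages,
       baseline = baseline_summary(vo2 = vo2_bl, rer = truth$rer_standing))
}

#' Simulate a speed-controlled time trial with VO2 on-kinetics
#'
#' The speed trace follows a target pacing profile under the treadmill
#' speed-controller limits (acceleration <= 0.50, deceleration <= 0.40
#' km·h⁻¹·s⁻¹) from the prescribed start speed. The true required MR is
#' the truth demand at each second's speed; the true aerobic MR relaxes
#' mono-exponentially (time constant `tau_on`) from the baseline MR toward
#' the instantaneous ceiling min(required, peak aerobic MR). The true
#' anaerobic capacity is the integral of (required - aerobic)/1000 and is
#' returned alongside the observable series, in which VO2 is the
#' Weir-equation inversion of the aerobic MR at TT RER plus noise.
#'
#' @param truth A [truth_params()].
#' @param start_speed Start speed, m·s⁻¹; default the final-stage speed
#'   (0.79 of peak) minus 2 km·h⁻¹, the treadmill protocol's rule.
#' @param target_speed Steady pacing target, m·s⁻¹; default the speed at
#'   which the truth demand is 102% of peak aerobic MR.
#' @param duration TT duration, s (default 240).
#' @param pacing Optional function `t -> target speed` overriding the
#'   default profile (steady target with a small sinusoidal drift and an
#'   end-spurt over the final 15 s, exercising both controller limits).
#' @return A list: `tt` (a [tt_series()]), `true_anc` (kJ·kg⁻¹),
#'   `true_required`, `true_aerobic` (per-second W·kg⁻¹). Uses the current
#'   RNG state.
#' @export
simulate_tt <- function(truth, start_speed = NULL, target_speed = NULL,
                        duration = 240, pacing = NULL) {
  stopifnot(inherits(truth, "truth_params"), duration >= 1)
  if (duration < 2 * truth$tau_on) {
    warning("TT duration shorter than 2*tau_on: kinetics are unresolved")
  }
  peak <- peak_aerobic_mr(truth$vo2peak)
  if (is.null(start_speed)) {
    start_speed <- speed_for_demand(truth, 0.79 * peak) - 2 / 3.6
  }
  if (is.null(target_speed)) {
    target_speed <- speed_for_demand(truth, 1.02 * peak)
  }
  if (is.null(pacing)) {
    pacing <- function(t) {
      v <- target_speed * (1 + 0.015 * sin(2 * pi * t / 120))
      spurt <- pmax(0, t - (duration - 15)) / 15 * 0.25
      v + spurt
    }
  }
  tgrid <- seq_len(duration)
  target <- vapply(tgrid, pacing, numeric(1))
  speed <- numeric(duration)
  prev <- start_speed
  for (i in tgrid) {
    dv <- target[i] - prev
    speed[i] <- prev + min(max(dv, -TT_DECEL_LIMIT), TT_ACCEL_LIMIT)
    prev <- speed[i]
  }
  req <- true_demand_mr(truth, speed)
  ceiling_mr <- pmin(req, peak)
  decay <- exp(-1 / truth$tau_on)
  ae <- numeric(duration)
  prev_ae <- truth$baseline_mr
  for (i in tgrid) {
    ae[i] <- ceiling_mr[i] + (prev_ae - ceiling_mr[i]) * decay
    prev_ae <- ae[i]
  }
  true_anc <- sum(req - ae) / 1000
  vo2 <- pmax(0, vo2_from_mr(ae, truth$rer_tt) +
                stats::rnorm(duration, 0, truth$noise_sd_vo2))
  list(
    tt = tt_series(tgrid, speed, vo2, rep(truth$rer_tt, duration),
                   expected_duration = duration),
    true_anc = true_anc,
    true_required = req,
    true_aerobic = ae
  )
}

#' Cohort-level distribution settings for the generator
#'
#' Participant-level truth parameters are drawn from normal distributions
#' whose defaults emulate the study cohort: GEC 4.39 ± 0.29 J·kg⁻¹·m⁻¹
#' (anchored at 3.13 m·s⁻¹), VO2peak 58 ± 6 mL·kg⁻¹·min⁻¹, standing
#' baseline MR 1.8 ± 0.2 W·kg⁻¹, a small positive demand-line intercept
#' 0.2 ± 0.5 W·kg⁻¹ (distinct from the standing MR), and on-kinetics
#' tau 25 ± 3 s.
#'
#' @param gec0_mean,gec0_sd GEC at the reference speed, J·kg⁻¹·m⁻¹.
#' @param vo2peak_mean,vo2peak_sd Peak oxygen uptake, mL·kg⁻¹·min⁻¹.
#' @param baseline_mean,baseline_sd Standing baseline MR, W·kg⁻¹.
#' @param intercept_mean,intercept_sd Demand-line intercept, W·kg⁻¹.
#' @param tau_mean,tau_sd VO2 on-kinetics time constant, s.
#' @param noise_sd_vo2 VO2 noise SD, mL·kg⁻¹·min⁻¹ (0.45 gives a
#'   stage-to-stage GEC SD of about 0.05 J·kg⁻¹·m⁻¹).
#' @param duration TT duration, s.
#' @param v_ref Reference speed for the GEC anchor, m·s⁻¹.
#' @param fractions Submaximal stage intensities (fractions of peak MR).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(gec0_mean = 4.39, gec0_sd = 0.29,
                          vo2peak_mean = 58, vo2peak_sd = 6,
                          baseline_mean = 1.8, baseline_sd = 0.2,
                          intercept_mean = 0.2, intercept_sd = 0.5,
                          tau_mean = 25, tau_sd = 3,
                          noise_sd_vo2 = 0.45, duration = 240,
                          v_ref = 3.13,
                          fractions = seq(0.57, 0.79, length.out = 5)) {
  cfg <- as.list(environment())
  sds <- c(cfg$gec0_sd, cfg$vo2peak_sd, cfg$baseline_sd, cfg$intercept_sd,
           cfg$tau_sd, cfg$noise_sd_vo2)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("distribution SDs must be finite and >= 0", call. = FALSE)
  }
  if (cfg$gec0_mean <= 0 || cfg$vo2peak_mean <= 0 || cfg$tau_mean <= 0) {
    stop("distribution means must be positive", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a cohort of synthetic participants
#'
#' Draws participant-level truth parameters from [cohort_config()]
#' distributions (mild truncation keeps every draw physiologically
#' admissible), then simulates the submaximal protocol and the time trial
#' for each participant. Deterministic given `seed`.
#'
#' @param n Number of participants (>= 1).
#' @param config A [cohort_config()].
#' @param seed Integer seed for all randomness (optional; uses the current
#'   RNG state when `NULL`).
#' @return A list of class `synthetic_cohort`; each element is a
#'   `synthetic_participant` with `id`, `truth`, `stages`, `baseline`,
#'   `tt` and `true_anc`.
#' @export
generate_cohort <- function(n, config = cohort_config(), seed = NULL) {
  stopifnot(n >= 1, inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    gec0 <- max(3.0, stats::rnorm(1, config$gec0_mean, config$gec0_sd))
    vo2peak <- max(35, stats::rnorm(1, config$vo2peak_mean,
                                    config$vo2peak_sd))
    bl <- max(0.8, stats::rnorm(1, config$baseline_mean, config$baseline_sd))
    b <- stats::rnorm(1, config$intercept_mean, config$intercept_sd)
    b <- min(max(b, -1.5), 2.5)
    tau <- max(10, stats::rnorm(1, config$tau_mean, config$tau_sd))
    truth <- truth_params(
      vo2peak = vo2peak, baseline_mr = bl, gec0 = gec0,
      v_ref = config$v_ref, demand_intercept = b, tau_on = tau,
      noise_sd_vo2 = config$noise_sd_vo2
    )
    sm <- simulate_submax(truth, fractions = config$fractions)
    tt <- simulate_tt(truth, duration = config$duration)
    out[[i]] <- structure(list(
      id = sprintf("P%02d", i),
      truth = truth,
      stages = sm$stages,
      baseline = sm$baseline,
      tt = tt$tt,
      true_anc = tt$true_anc
    ), class = "synthetic_participant")
  }
  structure(out, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, true AnC %.2f-%.2f kJ/kg\n",
              length(x), min(vapply(x, `[[`, numeric(1), "true_anc")),
              max(vapply(x, `[[`, numeric(1), "true_anc"))))
  invisible(x)
}

#' Write a cohort to the package's CSV/JSON fixture schemas
#'
#' Emits `stages.csv` (baseline rows flagged `stage = "BL"` at speed 0),
#' `tt.csv` and `truth.json` into a directory. `truth.json` is a
#' ground-truth sidecar for validation only; the analysis readers never
#' touch it. All writes are atomic (temp file + rename).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Writable output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stage_rows <- lapply(cohort, function(p) {
    st <- as.data.frame(p$stages)
    rbind(
      data.frame(participant_id = p$id, stage = "BL", speed = 0,
                 vo2 = p$baseline$vo2, rer = p$baseline$rer,
                 hr = NA_real_, lactate = NA_real_, rpe = NA_real_),
      data.frame(participant_id = p$id,
                 stage = paste0("SUB", seq_len(nrow(st))),
                 speed = st$speed, vo2 = st$vo2, rer = st$rer,
                 hr = st$hr, lactate = st$lactate, rpe = st$rpe)
    )
  })
  tt_rows <- lapply(cohort, function(p) {
    data.frame(participant_id = p$id, t = p$tt$t, speed = p$tt$speed,
               vo2 = p$tt$vo2, rer = p$tt$rer)
  })
  truth <- lapply(cohort, function(p) {
    c(list(id = p$id, true_anc = p$true_anc),
      unclass(p$truth))
  })
  stage_df <- if (length(stage_rows)) {
    do.call(rbind, stage_rows)
  } else {
    data.frame(participant_id = character(), stage = character(),
               speed = numeric(), vo2 = numeric(), rer = numeric(),
               hr = numeric(), lactate = numeric(), rpe = numeric())
  }
  tt_df <- if (length(tt_rows)) {
    do.call(rbind, tt_rows)
  } else {
    data.frame(participant_id = character(), t = numeric(),
               speed = numeric(), vo2 = numeric(), rer = numeric())
  }
  paths <- c(stages = file.path(dir, "stages.csv"),
             tt = file.path(dir, "tt.csv"),
             truth = file.path(dir, "truth.json"))
  atomic_write(paths[["stages"]], function(f)
    utils::write.csv(stage_df, f, row.names = FALSE))
  atomic_write(paths[["tt"]], function(f)
    utils::write.csv(tt_df, f, row.names = FALSE))
  atomic_write(paths[["truth"]], function(f)
    jsonlite::write_json(truth, f, auto_unbox = TRUE, digits = NA,
                         null = "null"))
  invisible(paths)
}
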