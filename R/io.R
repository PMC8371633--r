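# File schemas and the end-to-end pipeline. Schemas (all plain CSV):
#   stages.csv  participant_id,stage,speed,vo2,rer[,hr,lactate,rpe]
#               (baseline rows carry stage = "BL" at speed 0)
#   tt.csv      participant_id,t,speed,vo2,rer
#   results.csv one row per participant x model, fixed column order
# Speeds may arrive in km/h (speed_unit flag); stored internally in m/s.
# The 1% treadmill incline is metadata only: no grade-energy correction
# is applied.

atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("could not move temporary file into place at ", path,
         call. = FALSE)
  }
  invisible(path)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(cols, c("participant_id", "stage"))) {
    if (!is.numeric(df[[col]])) {
      stop("non-numeric values in column '", col, "' of ", path,
           call. = FALSE)
    }
  }
  invisible(df)
}

#' Read submaximal stages (and baselines) from CSV
#'
#' Parses the `stages.csv` schema: one row per participant per stage, with
#' baseline rows flagged `stage = "BL"`. Speeds are converted to m·s⁻¹ on
#' ingest when `speed_unit = "km/h"`; metabolic rate and gross energy cost
#' are derived per row.
#'
#' @param path Path to the CSV file.
#' @param speed_unit `"m/s"` (default) or `"km/h"`.
#' @return A named list (one element per participant), each a list with
#'   `stages` (a [stage_table()]) and `baseline` (a [baseline_summary()]
#'   or `NULL` when no BL row is present).
#' @export
read_stages <- function(path, speed_unit = c("m/s", "km/h")) {
  speed_unit <- match.arg(speed_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("participant_id", "stage", "speed", "vo2", "rer"),
                  path)
  key <- paste(df$participant_id, df$stage)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, stage) rows in ", path, ": ",
         paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  }
  lapply(split(df, df$participant_id), function(p) {
    bl_rows <- p$stage == "BL"
    baseline <- if (any(bl_rows)) {
      baseline_summary(vo2 = p$vo2[bl_rows][1], rer = p$rer[bl_rows][1])
    }
    p <- p[!bl_rows, , drop = FALSE]
    opt <- function(col) if (col %in% names(p)) p[[col]] else NULL
    stages <- stage_table(p$speed, vo2 = p$vo2, rer = p$rer,
                          hr = opt("hr"), lactate = opt("lactate"),
                          rpe = opt("rpe"), speed_unit = speed_unit)
    list(stages = stages, baseline = baseline)
  })
}

#' Read time-trial series from CSV
#'
#' Parses the `tt.csv` schema (`participant_id,t,speed,vo2,rer`). Records
#' not already on a 1-Hz integer grid are linearly interpolated onto one
#' with [resample_to_1hz()].
#'
#' @inheritParams read_stages
#' @param expected_duration Expected TT length in s (deviations warn).
#' @return A named list of [tt_series()], one per participant.
#' @export
read_tt <- function(path, speed_unit = c("m/s", "km/h"),
                    expected_duration = 240) {
  speed_unit <- match.arg(speed_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("participant_id", "t", "speed", "vo2", "rer"), path)
  if (speed_unit == "km/h") df$speed <- df$speed / 3.6
  lapply(split(df, df$participant_id), function(p) {
    p <- p[order(p$t), , drop = FALSE]
    on_grid <- all(p$t == round(p$t)) && all(diff(p$t) == 1)
    if (on_grid) {
      tt_series(p$t, p$speed, p$vo2, p$rer,
                expected_duration = expected_duration)
    } else {
      resample_to_1hz(p[, c("t", "speed", "vo2", "rer")])
    }
  })
}

#' Study configuration
#'
#' Validated bundle of analysis settings: which demand models to run, the
#' baseline averaging window, the expected TT duration, the input speed
#' unit, the optional gas-exchange lag shift, and the seed.
#'
#' @param models Demand-model labels to run (subset of [anc_models()]);
#'   default the four primary models.
#' @param baseline_window Baseline VO2 averaging window, s (default 60).
#' @param tt_duration Expected TT duration, s (default 240).
#' @param speed_unit Unit of input speeds, `"m/s"` or `"km/h"`.
#' @param lag_shift Fixed gas-exchange time shift, s (default 0).
#' @param seed Optional integer seed.
#' @return A list of class `study_config`.
#' @export
study_config <- function(models = anc_models(primary_only = TRUE),
                         baseline_window = 60, tt_duration = 240,
                         speed_unit = c("m/s", "km/h"), lag_shift = 0,
                         seed = NULL) {
  speed_unit <- match.arg(speed_unit)
  bad <- setdiff(models, anc_models())
  if (length(bad)) {
    stop("unknown model label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(baseline_window > 0, tt_duration > 0)
  structure(list(models = models, baseline_window = baseline_window,
                 tt_duration = tt_duration, speed_unit = speed_unit,
                 lag_shift = lag_shift, seed = seed),
            class = "study_config")
}

#' Run the full per-participant, cross-model pipeline
#'
#' For every participant and every configured demand model, computes the
#' time-trial anaerobic capacity ([compute_anc()]); then assembles the
#' participants × models AnC matrix and runs the agreement battery
#' ([agreement_report()]). Deterministic given the inputs and config.
#'
#' @param data Either a [generate_cohort()] result, or a directory
#'   containing `stages.csv` and `tt.csv` in the package schemas.
#' @param config A [study_config()].
#' @param verbose Log one line per participant-model with the AnC and
#'   flags.
#' @return A list of class `anc_pipeline` with `results` (data.frame, one
#'   row per participant × model, fixed column order) and `agreement` (an
#'   [agreement_report()] on the AnC matrix, or `NULL` when fewer than 3
#'   participants or 2 models).
#' @export
run_pipeline <- function(data, config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  if (inherits(data, "synthetic_cohort")) {
    participants <- lapply(data, function(p)
      list(id = p$id, stages = p$stages, baseline = p$baseline, tt = p$tt))
  } else if (is.character(data) && length(data) == 1 && dir.exists(data)) {
    st <- read_stages(file.path(data, "stages.csv"),
                      speed_unit = config$speed_unit)
    tts <- read_tt(file.path(data, "tt.csv"),
                   speed_unit = config$speed_unit,
                   expected_duration = config$tt_duration)
    ids <- sort(union(names(st), names(tts)))
    participants <- lapply(ids, function(id) {
      if (is.null(st[[id]])) {
        stop("participant ", id, " has a time trial but no stages",
             call. = FALSE)
      }
      if (is.null(tts[[id]])) {
        stop("participant ", id, " has stages but no time trial",
             call. = FALSE)
      }
      list(id = id, stages = st[[id]]$stages,
           baseline = st[[id]]$baseline, tt = tts[[id]])
    })
  } else {
    stop("data must be a synthetic_cohort or a directory path",
         call. = FALSE)
  }
  needs_bl <- grepl("\\+Y", config$models)
  rows <- list()
  for (p in participants) {
    if (any(needs_bl) && is.null(p$baseline)) {
      stop("participant ", p$id, " has no baseline (stage = \"BL\") row, ",
           "required by model(s): ",
           paste(config$models[needs_bl], collapse = ", "), call. = FALSE)
    }
    for (m in config$models) {
      res <- tryCatch(
        compute_anc(p$stages, p$baseline, p$tt, m,
                    lag_shift = config$lag_shift),
        error = function(e) {
          stop("participant ", p$id, ", model ", m, ": ",
               conditionMessage(e), call. = FALSE)
        })
      if (verbose) {
        message(sprintf(
          "%s %-8s AnC %.3f kJ/kg (neg s: %d%s)", p$id, m, res$anc,
          res$n_negative_seconds,
          if (res$extrapolated) ", extrapolated" else ""))
      }
      rows[[length(rows) + 1]] <-
        cbind(participant_id = p$id, as.data.frame(res))
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  agreement <- NULL
  ids <- unique(results$participant_id)
  if (length(ids) >= 3 && length(config$models) >= 2) {
    mat <- matrix(NA_real_, nrow = length(ids),
                  ncol = length(config$models),
                  dimnames = list(ids, config$models))
    for (i in seq_len(nrow(results))) {
      mat[results$participant_id[i], results$model_id[i]] <- results$anc[i]
    }
    agreement <- agreement_report(mat)
  }
  structure(list(results = results, agreement = agreement,
                 config = config),
            class = "anc_pipeline")
}

#' @export
print.anc_pipeline <- function(x, ...) {
  ids <- unique(x$results$participant_id)
  cat(sprintf("AnC pipeline: %d participants x %d models\n", length(ids),
              length(unique(x$results$model_id))))
  agg <- stats::aggregate(anc ~ model_id, x$results, mean)
  agg$anc <- round(agg$anc, 3)
  names(agg) <- c("model", "mean AnC (kJ/kg)")
  print(agg, row.names = FALSE)
  if (!is.null(x$agreement)) {
    o <- x$agreement$omnibus
    cat(sprintf("Omnibus: F(%.2f, %.2f) = %.2f, p = %.4g, eta^2 = %.3f, SEM = %.3f\n",
                o$df_effect, o$df_error, o$f_statistic, o$p_value,
                o$eta_squared, o$sem))
  }
  invisible(x)
}

#' Write pipeline results to CSV
#'
#' Fixed, documented column order; atomic write (temp file + rename).
#'
#' @param results The `results` data.frame of [run_pipeline()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  cols <- c("participant_id", "model_id", "anc", "o2_deficit",
            "mean_required_mr", "mean_aerobic_mr", "anaerobic_fraction",
            "gec_tt_avg", "mr_req_pct_peak", "vo2peak", "distance",
            "duration", "n_negative_seconds", "extrapolated")
  stopifnot(all(cols %in% names(results)))
  atomic_write(path, function(f)
    utils::write.csv(results[, cols], f, row.names = FALSE))
}
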