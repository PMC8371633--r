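# Between-model agreement statistics: Bland-Altman limits of agreement,
# typical error, Hedges g_av, one-way repeated-measures ANOVA with
# Greenhouse-Geisser handling of sphericity, ICC(consistency) and the
# ICC-based standard error of measurement.

#' Hedges g_av paired effect size
#'
#' Standardized mean difference for paired samples: the mean difference
#' divided by the average of the two condition SDs, multiplied by the
#' small-sample correction J = 1 - 3/(4(n-1) - 1).
#'
#' @param a,b Paired numeric vectors (n >= 3).
#' @return Hedges g_av (dimensionless); `Inf` (with a warning) when the
#'   SDs are zero but the mean difference is not.
#' @export
hedges_gav <- function(a, b) {
  check_paired(a, b)
  n <- length(a)
  md <- mean(a - b)
  s_av <- (stats::sd(a) + stats::sd(b)) / 2
  j <- 1 - 3 / (4 * (n - 1) - 1)
  if (s_av == 0) {
    if (md == 0) return(0)
    warning("zero condition SDs with a nonzero mean difference: infinite effect size")
    return(sign(md) * Inf)
  }
  j * md / s_av
}

check_paired <- function(a, b) {
  if (length(a) != length(b)) {
    stop("paired samples differ in length", call. = FALSE)
  }
  if (length(a) < 3) {
    stop("at least 3 pairs are required", call. = FALSE)
  }
  invisible(NULL)
}

#' Bland-Altman agreement between two paired measurements
#'
#' Differences d = a - b summarized as mean difference, SD, 95% limits of
#' agreement (mean ± 1.96 SD), typical error (SD(d)/sqrt(2)), a paired
#' t-test on the differences, and Hedges g_av.
#'
#' @param a,b Paired per-participant values (n >= 3).
#' @return A list of class `pairwise_agreement` with `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `typical_error`, `t_statistic`,
#'   `p_value`, `hedges_gav`, `n`.
#' @export
bland_altman <- function(a, b) {
  check_paired(a, b)
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  tt <- if (sdd == 0) {
    list(statistic = if (md == 0) 0 else sign(md) * Inf,
         p.value = if (md == 0) 1 else 0)
  } else {
    stats::t.test(d)
  }
  structure(list(
    mean_diff = md,
    sd_diff = sdd,
    loa_low = md - 1.96 * sdd,
    loa_high = md + 1.96 * sdd,
    typical_error = sdd / sqrt(2),
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    hedges_gav = hedges_gav(a, b),
    n = length(a)
  ), class = "pairwise_agreement")
}

#' @export
print.pairwise_agreement <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean diff %.3f [LoA %.3f, %.3f]\n",
              x$n, x$mean_diff, x$loa_low, x$loa_high))
  cat(sprintf("  typical error %.3f, paired t = %.2f (p = %.4g), Hedges g_av = %.2f\n",
              x$typical_error, x$t_statistic, x$p_value, x$hedges_gav))
  invisible(x)
}

check_matrix <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (anyNA(values)) {
    stop("incomplete matrix: missing cells are not imputed", call. = FALSE)
  }
  if (nrow(values) < 3 || ncol(values) < 2) {
    stop("need >= 3 participants (rows) and >= 2 conditions (columns)",
         call. = FALSE)
  }
  values
}

# One-way repeated-measures sum-of-squares decomposition:
# SS_total = SS_subjects + SS_condition + SS_residual.
rm_ss <- function(values) {
  n <- nrow(values); k <- ncol(values)
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  ss_subj <- k * sum((rowMeans(values) - grand)^2)
  ss_cond <- n * sum((colMeans(values) - grand)^2)
  list(n = n, k = k,
       ss_total = ss_total, ss_subjects = ss_subj, ss_condition = ss_cond,
       ss_residual = ss_total - ss_subj - ss_cond)
}

# Greenhouse-Geisser epsilon from the double-centered condition covariance.
gg_epsilon <- function(values) {
  k <- ncol(values)
  if (k == 2) return(1)
  S <- stats::cov(values)
  Sc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

#' One-way repeated-measures ANOVA across computational models
#'
#' Within-subjects ANOVA on a complete participants × models matrix, with
#' Mauchly's sphericity test, a Greenhouse-Geisser correction of the
#' degrees of freedom applied when sphericity is rejected (Mauchly
#' p <= 0.05) and epsilon <= 0.75, the eta-squared effect size computed
#' against the total sum of squares (between-subject variance included),
#' ICC/SEM reliability summaries, and Bonferroni-adjusted pairwise paired
#' t-tests.
#'
#' @param values Complete numeric matrix, participants in rows, models in
#'   columns (n >= 3, k >= 2). Column names label the models.
#' @return A list of class `omnibus_comparison`: `f_statistic`,
#'   `df_effect`, `df_error` (GG-corrected when applied), `epsilon_gg`,
#'   `mauchly_p`, `gg_applied`, `p_value`, `eta_squared`, `icc`, `sem`,
#'   `bonferroni_pairwise` (data.frame of adjusted pairwise p-values) and
#'   the sum-of-squares decomposition `ss`.
#' @export
rm_anova <- function(values) {
  values <- check_matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("m", seq_len(ncol(values)))
  }
  ss <- rm_ss(values)
  n <- ss$n; k <- ss$k
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_cond <- ss$ss_condition / df1
  ms_res <- ss$ss_residual / df2
  if (ms_res <= .Machine$double.eps * max(1, ms_cond)) {
    f <- if (ss$ss_condition <= .Machine$double.eps) 0 else Inf
    p <- if (f == 0) 1 else 0
  } else {
    f <- ms_cond / ms_res
    p <- NA_real_  # filled after the sphericity decision
  }
  eps <- gg_epsilon(values)
  mauchly_p <- tryCatch({
    if (k == 2) NA_real_ else {
      fit <- stats::lm(values ~ 1)
      stats::mauchly.test(fit, X = ~1)$p.value
    }
  }, error = function(e) NA_real_)
  gg_applied <- isTRUE(!is.na(mauchly_p) && mauchly_p <= 0.05 &&
                         eps <= 0.75)
  if (gg_applied) {
    df1_used <- eps * df1
    df2_used <- eps * df2
  } else {
    df1_used <- df1
    df2_used <- df2
  }
  if (is.na(p)) p <- stats::pf(f, df1_used, df2_used, lower.tail = FALSE)
  pairs <- utils::combn(colnames(values), 2)
  m <- ncol(pairs)
  praw <- vapply(seq_len(m), function(i) {
    d <- values[, pairs[1, i]] - values[, pairs[2, i]]
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) 1 else 0
    } else {
      stats::t.test(d)$p.value
    }
  }, numeric(1))
  pw <- data.frame(
    model_a = pairs[1, ], model_b = pairs[2, ],
    mean_diff = vapply(seq_len(m), function(i)
      mean(values[, pairs[1, i]] - values[, pairs[2, i]]), numeric(1)),
    p_raw = praw,
    p_bonferroni = pmin(1, praw * m),
    stringsAsFactors = FALSE
  )
  structure(list(
    f_statistic = f,
    df_effect = df1_used,
    df_error = df2_used,
    epsilon_gg = eps,
    mauchly_p = mauchly_p,
    gg_applied = gg_applied,
    p_value = p,
    eta_squared = if (ss$ss_total == 0) 0 else ss$ss_condition / ss$ss_total,
    icc = icc_consistency(values),
    sem = sem_from_icc(values),
    bonferroni_pairwise = pw,
    ss = ss
  ), class = "omnibus_comparison")
}

#' @export
print.omnibus_comparison <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%.2f, %.2f) = %.2f, p = %.4g%s\n",
              x$df_effect, x$df_error, x$f_statistic, x$p_value,
              if (x$gg_applied) " (Greenhouse-Geisser corrected)" else ""))
  cat(sprintf("  epsilon_GG = %.3f, Mauchly p = %s, eta^2 = %.3f\n",
              x$epsilon_gg,
              if (is.na(x$mauchly_p)) "NA" else sprintf("%.4g", x$mauchly_p),
              x$eta_squared))
  cat(sprintf("  ICC = %.3f, SEM = %.3f\n", x$icc, x$sem))
  cat("  Bonferroni pairwise:\n")
  print(x$bonferroni_pairwise, row.names = FALSE)
  invisible(x)
}

#' Intraclass correlation (consistency) from repeated-measures mean squares
#'
#' (BMS - WMS) / BMS, where BMS is the between-subjects mean square and
#' WMS the within-subjects mean square (condition + residual pooled) of
#' the repeated-measures decomposition.
#'
#' @param values Complete participants × models matrix.
#' @return The ICC (dimensionless); `NA` with a warning when BMS = 0.
#' @export
icc_consistency <- function(values) {
  values <- check_matrix(values)
  ss <- rm_ss(values)
  bms <- ss$ss_subjects / (ss$n - 1)
  wms <- (ss$ss_condition + ss$ss_residual) / (ss$n * (ss$k - 1))
  if (bms == 0) {
    warning("between-subjects mean square is zero: ICC undefined")
    return(NA_real_)
  }
  (bms - wms) / bms
}

#' Standard error of measurement from the ICC
#'
#' SEM = SD_pooled * sqrt(1 - ICC), with SD_pooled the pooled SD of the
#' model columns (average of the column variances, in quadrature).
#'
#' @param values Complete participants × models matrix.
#' @param icc Optional precomputed ICC; default [icc_consistency()].
#' @return SEM in the units of `values`.
#' @export
sem_from_icc <- function(values, icc = NULL) {
  values <- check_matrix(values)
  if (is.null(icc)) icc <- icc_consistency(values)
  sd_pooled <- sqrt(mean(apply(values, 2, stats::var)))
  sd_pooled * sqrt(max(0, 1 - icc))
}

#' Full between-model agreement report
#'
#' The paper-style statistical battery on a participants × models matrix:
#' the omnibus repeated-measures comparison ([rm_anova()], including
#' ICC/SEM) plus Bland-Altman statistics for every model pair.
#'
#' @param values Complete numeric matrix, participants × models (named
#'   columns).
#' @return A list of class `agreement_report` with elements `omnibus`
#'   (an `omnibus_comparison`) and `pairwise` (one data.frame row per
#'   model pair with the Bland-Altman quantities and Bonferroni-adjusted
#'   p-values).
#' @export
agreement_report <- function(values) {
  values <- check_matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("m", seq_len(ncol(values)))
  }
  omni <- rm_anova(values)
  pairs <- utils::combn(colnames(values), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    ba <- bland_altman(values[, pairs[1, i]], values[, pairs[2, i]])
    data.frame(model_a = pairs[1, i], model_b = pairs[2, i],
               mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
               loa_low = ba$loa_low, loa_high = ba$loa_high,
               typical_error = ba$typical_error,
               t_statistic = ba$t_statistic, p_value = ba$p_value,
               hedges_gav = ba$hedges_gav,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$p_bonferroni <- omni$bonferroni_pairwise$p_bonferroni
  structure(list(omnibus = omni, pairwise = pw),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  print(x$omnibus)
  cat("Pairwise Bland-Altman:\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize an agreement report to JSON
#'
#' @param report An `agreement_report`.
#' @return A JSON string.
#' @export
agreement_to_json <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  omni <- unclass(report$omnibus)
  jsonlite::toJSON(list(omnibus = omni, pairwise = report$pairwise),
                   auto_unbox = TRUE, digits = NA, dataframe = "rows",
                   na = "null")
}
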