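# Shared fixtures: the group-mean submaximal protocol (five stages plus a
# standing baseline) and small independent oracles used across tests.

group_mean_stages <- function() {
  stage_table(speed = c(2.60, 2.87, 3.13, 3.40, 3.66),
              mr = c(11.5, 12.6, 13.7, 14.9, 16.1))
}

# stage table carrying the published per-stage gross energy costs directly
group_mean_stages_gec <- function() {
  stage_table(speed = c(2.60, 2.87, 3.13, 3.40, 3.66),
              gec = c(4.42, 4.39, 4.37, 4.38, 4.38))
}

group_mean_baseline <- function() baseline_summary(mr_bl = 1.8)

# normal-equations OLS oracle, independent of lm()
ols_oracle <- function(x, y, degree = 1) {
  X <- vapply(0:degree, function(p) x^p, numeric(length(x)))
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  list(coef = as.numeric(beta), sse = sum(res^2))
}

# brute-force all-windows scan oracle for rolling_peak
rolling_peak_oracle <- function(x, w) {
  max(vapply(seq_len(length(x) - w + 1),
             function(i) mean(x[i:(i + w - 1)]), numeric(1)))
}

# brute-force repeated-measures sums of squares via explicit loops
rm_ss_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_tot <- 0; ss_subj <- 0; ss_cond <- 0
  for (i in seq_len(n)) {
    ss_subj <- ss_subj + k * (mean(m[i, ]) - grand)^2
    for (j in seq_len(k)) ss_tot <- ss_tot + (m[i, j] - grand)^2
  }
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(m[, j]) - grand)^2
  list(ss_total = ss_tot, ss_subjects = ss_subj, ss_condition = ss_cond,
       ss_residual = ss_tot - ss_subj - ss_cond)
}

# quiet constructor for short synthetic TTs (length-240 warning suppressed)
short_tt <- function(t, speed, vo2, rer) {
  tt_series(t, speed, vo2, rer, expected_duration = length(t))
}
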