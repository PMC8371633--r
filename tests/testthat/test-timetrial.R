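test_that("1-Hz resampling interpolates linearly and holds the edges", {
  # already on the grid: identity
  df <- data.frame(t = 1:10, speed = seq(3, 4.8, length.out = 10),
                   vo2 = seq(10, 50, length.out = 10), rer = rep(1, 10))
  out <- resample_to_1hz(df)
  expect_equal(out$speed, df$speed)
  expect_equal(out$vo2, df$vo2)
  # two samples: midpoint value at t = 1
  mid <- resample_to_1hz(data.frame(t = c(0, 2), y = c(10, 20)))
  expect_equal(mid$y[mid$t == 1], 15)
  # 2.46 Hz samples of a linear ramp: exact at integer seconds
  ts <- seq(0, 240, by = 1 / 2.46)
  ramp <- resample_to_1hz(data.frame(t = ts, y = 2 + 0.01 * ts))
  expect_equal(ramp$y, 2 + 0.01 * ramp$t, tolerance = 1e-12)
  # no extrapolation: edges held constant
  edge <- resample_to_1hz(data.frame(t = c(1.5, 3.5), y = c(10, 20)),
                          grid = 0:5)
  expect_equal(edge$y, c(10, 10, 12.5, 17.5, 20, 20))
  expect_error(resample_to_1hz(data.frame(t = 1, y = 2)), "two samples")
  expect_error(resample_to_1hz(data.frame(t = c(2, 1), y = c(1, 2))),
               "non-decreasing")
})

test_that("stage window averaging covers 2:50-3:50 inclusively", {
  series <- data.frame(t = 0:250, vo2 = rep(41.2, 251), rer = rep(0.9, 251))
  expect_equal(stage_window_average(series, 0)$vo2, 41.2)
  # linear ramp: the window mean is the value at the midpoint t = 200
  series$vo2 <- 10 + 0.1 * series$t
  expect_equal(stage_window_average(series, 0)$vo2, 10 + 0.1 * 200)
  expect_error(stage_window_average(series, 100), "insufficient")
})

test_that("rolling peak equals the brute-force window scan", {
  expect_equal(rolling_peak(rep(7.5, 60), 30), 7.5)
  x <- sort(runif(100))
  expect_equal(rolling_peak(x, 30), mean(x[71:100]))
  set.seed(77)
  for (i in 1:25) {
    n <- sample(30:120, 1)
    w <- sample(c(5, 30, n), 1)
    y <- rnorm(n)
    expect_equal(rolling_peak(y, w), rolling_peak_oracle(y, w),
                 tolerance = 1e-12)
  }
  expect_error(rolling_peak(rnorm(10), 30), "shorter")
  expect_error(rolling_peak(rnorm(10), 2.5), "positive integer")
})

test_that("aerobic and anaerobic series follow the per-second decomposition", {
  tt <- short_tt(1:60, rep(4.7, 60), rep(58, 60), rep(1.14, 60))
  ae <- aerobic_mr_series(tt)
  expect_equal(ae, rep(metabolic_rate(58, 1.00), 60))
  tt_clamped <- short_tt(1:60, rep(4.7, 60), rep(58, 60), rep(1.00, 60))
  expect_equal(aerobic_mr_series(tt_clamped), ae)
  tt0 <- short_tt(1:60, rep(4.7, 60), rep(0, 60), rep(1, 60))
  expect_equal(aerobic_mr_series(tt0), rep(0, 60))
  expect_equal(anaerobic_mr_series(rep(20, 5), rep(15, 5)), rep(5, 5))
  expect_equal(anaerobic_mr_series(rep(20, 5), rep(20, 5)), rep(0, 5))
  expect_error(anaerobic_mr_series(1:4, 1:5), "length")
})

test_that("integration follows the rectangle rule and is additive", {
  expect_equal(integrate_anc(rep(5, 240)), 1.2)
  expect_equal(integrate_anc(rep(0, 100)), 0)
  expect_error(integrate_anc(numeric(0)), "empty")
  mixed <- c(3, -1, 2, -4, 5)
  expect_equal(integrate_anc(mixed), sum(mixed) / 1000)
  set.seed(5)
  an <- rnorm(240)
  expect_equal(integrate_anc(an[1:120]) + integrate_anc(an[121:240]),
               integrate_anc(an))
})

test_that("time-trial series validation enforces the 1-s grid", {
  expect_error(tt_series(c(1, 3), c(4, 4), c(50, 50), c(1, 1)), "1-s")
  expect_error(tt_series(1:2, c(-1, 4), c(50, 50), c(1, 1)), "negative")
  expect_warning(tt_series(1:100, rep(4, 100), rep(50, 100), rep(1, 100)),
                 "differs")
})

test_that("zero deficit when aerobic supply matches the demand model", {
  speed <- 3 + sin(seq(0, 2 * pi, length.out = 120))
  g <- 4.3
  tt <- short_tt(1:120, speed, vo2_from_mr(g * speed, 1.00), rep(1, 120))
  fg <- fixed_gec_model(stage_table(speed = 3, gec = g))
  res <- compute_anc(stage_table(speed = 3, gec = g),
                     baseline_summary(mr_bl = 1.8), tt, fg)
  expect_equal(res$anc, 0, tolerance = 1e-12)
  expect_equal(res$anaerobic_fraction, 0, tolerance = 1e-10)
})

test_that("fixed-GEC AnC equals cost times distance minus aerobic energy", {
  set.seed(9)
  speed <- runif(240, 3.5, 5.5)
  vo2 <- runif(240, 40, 58)
  tt <- tt_series(1:240, speed, vo2, rep(1, 240))
  st <- stage_table(speed = c(2.6, 3.6), gec = c(4.4, 4.36))
  res <- compute_anc(st, baseline_summary(mr_bl = 1.8), tt, "GEC_AVG")
  g <- mean(c(4.4, 4.36))
  dist <- sum(speed)  # independent distance computation, dt = 1 s
  expect_equal(res$anc,
               (g * dist - sum(metabolic_rate(vo2, 1))) / 1000,
               tolerance = 1e-10)
  expect_equal(res$distance, dist)
  expect_equal(res$gec_tt_avg, g)  # fixed models return their GEC exactly
})

test_that("mono-exponential aerobic supply gives the closed-form deficit", {
  # group-mean cartoon: constant TT speed, required MR from the 5+Y fit,
  # aerobic MR relaxing exponentially from baseline toward the peak
  m <- demand_model("5+Y_LIN", group_mean_stages(), group_mean_baseline())
  R <- required_mr(m, 4.7)
  P <- peak_aerobic_mr(58)
  a0 <- 1.8; tau <- 25; T <- 240
  q <- exp(-1 / tau)
  ae <- P + (a0 - P) * q^(1:T)
  tt <- tt_series(1:T, rep(4.7, T), vo2_from_mr(ae, 1.00), rep(1, T))
  res <- compute_anc(group_mean_stages(), group_mean_baseline(), tt, m,
                     vo2peak = 58)
  # geometric closed form of the rectangle-rule integral
  analytic <- ((R - P) * T + (P - a0) * q * (1 - q^T) / (1 - q)) / 1000
  expect_equal(res$anc, analytic, tolerance = 1e-10)
  expect_equal(res$o2_deficit / res$anc, 47.801, tolerance = 1e-10)
  expect_equal(res$mr_req_pct_peak, 100 * R / P, tolerance = 1e-10)
  expect_true(res$extrapolated)
})

test_that("a uniformly higher demand model never yields less AnC", {
  set.seed(21)
  speed <- runif(120, 3, 5)
  tt <- short_tt(1:120, speed, runif(120, 40, 55), rep(1, 120))
  st <- stage_table(speed = c(2.6, 3.0, 3.4), gec = c(4.3, 4.3, 4.3))
  bl <- baseline_summary(mr_bl = 1.8)
  lo <- fixed_gec_model(st, "avg")
  hi <- fixed_gec_model(stage_table(speed = 3, gec = 4.5), "avg")
  expect_gte(compute_anc(st, bl, tt, hi)$anc,
             compute_anc(st, bl, tt, lo)$anc)
})

test_that("compute_anc accepts registry labels and reports peak-relative MR", {
  coh <- generate_cohort(1, seed = 3)
  p <- coh[[1]]
  res <- compute_anc(p$stages, p$baseline, p$tt, "5-Y_LIN")
  expect_equal(res$model_id, "5-Y_LIN")
  expect_equal(res$vo2peak, rolling_peak(p$tt$vo2, 30))
  expect_equal(res$mr_req_pct_peak,
               100 * res$mean_required_mr / peak_aerobic_mr(res$vo2peak))
  expect_equal(res$o2_deficit, res$anc * 1000 * 0.047801)
  df <- as.data.frame(res)
  expect_equal(nrow(df), 1)
  expect_equal(df$anc, res$anc)
})
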