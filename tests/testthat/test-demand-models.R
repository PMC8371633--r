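test_that("group-mean regression fits reproduce the frozen oracle values", {
  st <- group_mean_stages()
  bl <- group_mean_baseline()
  with_y <- fit_speed_mr(st, bl, include_baseline = TRUE)
  # normal-equations oracle on (0,1.8),(2.60,11.5)...(3.66,16.1)
  expect_equal(unname(with_y$coefficients[["intercept"]]), 1.692492,
               tolerance = 1e-6)
  expect_equal(unname(with_y$coefficients[["slope"]]), 3.859837,
               tolerance = 1e-6)
  expect_equal(with_y$n_stages_used, 5L)
  without_y <- fit_speed_mr(st, include_baseline = FALSE)
  expect_equal(unname(without_y$coefficients[["intercept"]]), 0.1693285,
               tolerance = 1e-6)
  expect_equal(unname(without_y$coefficients[["slope"]]), 4.3392949,
               tolerance = 1e-6)
})

test_that("OLS fits agree with a normal-equations oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    x <- sort(runif(n, 1, 6))
    y <- 1 + 4 * x + rnorm(n, 0, 0.5)
    st <- stage_table(speed = x, mr = y)
    degree <- if (n >= 4 && i %% 3 == 0) 2 else 1
    form <- if (degree == 2) "quadratic" else "linear"
    fit <- fit_speed_mr(st, form = form)
    oracle <- ols_oracle(x, y, degree)
    expect_equal(unname(fit$coefficients), oracle$coef, tolerance = 1e-10)
    expect_equal(fit$see, sqrt(oracle$sse / (n - degree - 1)),
                 tolerance = 1e-8)
  }
})

test_that("perfectly collinear stages give an exact fit", {
  st <- stage_table(speed = c(2, 3, 4, 5), mr = 4.3 * c(2, 3, 4, 5))
  fit <- fit_speed_mr(st)
  expect_equal(unname(fit$coefficients[["slope"]]), 4.3, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients[["intercept"]]), 0,
               tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  expect_lt(fit$see, 1e-8)
  # a baseline point already on the line does not change the fit
  bl <- baseline_summary(mr_bl = 0)
  fit_bl <- fit_speed_mr(st, bl, include_baseline = TRUE)
  expect_equal(unname(fit_bl$coefficients), unname(fit$coefficients),
               tolerance = 1e-9)
})

test_that("degenerate fits are rejected with diagnostics", {
  expect_error(fit_speed_mr(stage_table(speed = 3, mr = 12)),
               "underdetermined")
  expect_error(fit_speed_mr(stage_table(speed = c(3, 4), mr = c(12, 16)),
                            form = "quadratic"), "underdetermined")
  expect_error(fit_speed_mr(stage_table(speed = c(3, 3), mr = c(12, 16))),
               "singular")
  expect_error(fit_speed_mr(stage_table(speed = c(2, 3), mr = c(9, 12)),
                            include_baseline = TRUE), "baseline")
  # exact two-point fit has no residual df: SEE undefined, r2 = 1
  fit2 <- fit_speed_mr(stage_table(speed = c(3, 4), mr = c(12.5, 16)))
  expect_true(is.na(fit2$see))
  expect_equal(fit2$r2, 1)
})

test_that("fixed-GEC models average or take the last stage cost", {
  st <- group_mean_stages_gec()
  avg <- fixed_gec_model(st, "avg")
  expect_equal(avg$gec_value, mean(c(4.42, 4.39, 4.37, 4.38, 4.38)))
  expect_equal(round(avg$gec_value, 2), 4.39)
  last <- fixed_gec_model(st, "last")
  expect_equal(last$gec_value, 4.38)
  one <- stage_table(speed = 3, gec = 4.5)
  expect_equal(fixed_gec_model(one, "avg")$gec_value,
               fixed_gec_model(one, "last")$gec_value)
  expect_error(fixed_gec_model(st[0, ], "avg"), "empty")
})

test_that("required MR evaluates the demand model at any speed", {
  # exact-recovery construction gives a model with known coefficients
  sp <- c(2.6, 3.0, 3.4)
  lin <- fit_speed_mr(stage_table(speed = sp, mr = 1.69 + 3.85 * sp))
  expect_equal(required_mr(lin, 4.7), 19.785, tolerance = 1e-8)
  expect_equal(required_mr(lin, 0), 1.69, tolerance = 1e-9)
  fg <- fixed_gec_model(stage_table(speed = 3, gec = 4.39))
  expect_equal(required_mr(fg, 4.7), 4.39 * 4.7)
  expect_equal(required_mr(fg, 0), 0)
  # homogeneity of degree 1 for fixed-GEC demand
  v <- c(1.3, 2.9, 5.1)
  expect_equal(required_mr(fg, 2 * v), 2 * required_mr(fg, v))
  expect_error(required_mr(fg, -1), "non-negative")
})

test_that("model GEC decreases with speed iff the intercept is positive", {
  sp <- c(2.6, 3.0, 3.4)
  v <- seq(2, 6, by = 0.5)
  for (b in c(1.69, -0.8, 0)) {
    m <- fit_speed_mr(stage_table(speed = sp, mr = b + 4.3 * sp))
    g <- gec_from_model(m, v)
    if (b > 0) expect_true(all(diff(g) < 0))
    if (b < 0) expect_true(all(diff(g) > 0))
    if (b == 0) expect_equal(diff(g), rep(0, length(v) - 1),
                             tolerance = 1e-10)
  }
  m <- fit_speed_mr(stage_table(speed = sp, mr = 1.69 + 3.85 * sp))
  expect_equal(round(gec_from_model(m, 4.7), 2), 4.21)
  m2 <- fit_speed_mr(stage_table(speed = sp, mr = 0.18 + 4.32 * sp))
  expect_equal(round(gec_from_model(m2, 3.66), 2), 4.37)
  fg <- fixed_gec_model(stage_table(speed = 3, gec = 4.2))
  expect_equal(gec_from_model(fg, v), rep(4.2, length(v)))
  expect_error(gec_from_model(fg, 0), "undefined")
})

test_that("GEC percentage RMSE matches a per-stage loop oracle", {
  fg <- fixed_gec_model(stage_table(speed = 3, gec = 4.4))
  own <- stage_table(speed = c(2.5, 3.5), gec = c(4.4, 4.4))
  expect_equal(rmse_percent_gec(fg, own), 0)
  # measured costs engineered for exactly +1% / -1% relative model error
  st <- stage_table(speed = c(2.5, 3.5), gec = c(4.4 / 1.01, 4.4 / 0.99))
  expect_equal(rmse_percent_gec(fg, st), 1.0, tolerance = 1e-12)
  # group-mean regression vs the published stage costs, loop oracle
  m <- demand_model("5+Y_LIN", group_mean_stages_gec(),
                    group_mean_baseline())
  st2 <- group_mean_stages_gec()
  acc <- 0
  for (i in seq_len(nrow(st2))) {
    pred <- required_mr(m, st2$speed[i]) / st2$speed[i]
    acc <- acc + (100 * (pred - st2$gec[i]) / st2$gec[i])^2
  }
  expect_equal(rmse_percent_gec(m, st2), sqrt(acc / nrow(st2)),
               tolerance = 1e-12)
})

test_that("the model registry builds all nine demand models", {
  st <- group_mean_stages()
  bl <- group_mean_baseline()
  expect_length(anc_models(), 9)
  expect_length(anc_models(primary_only = TRUE), 4)
  for (lab in anc_models()) {
    m <- demand_model(lab, st, bl)
    expect_s3_class(m, "speed_mr_model")
    expect_equal(m$label, lab)
  }
  expect_error(demand_model("6-Y_LIN", st, bl), "unknown demand model")
  # reduced-stage models fit the highest-speed subset, baseline excluded
  m2 <- demand_model("2-Y_LIN", st, bl)
  direct <- fit_speed_mr(st[4:5, ])
  expect_equal(m2$coefficients, direct$coefficients)
  expect_false(m2$include_baseline)
  expect_equal(m2$n_stages_used, 2L)
  expect_equal(demand_model("5+Y_POL", st, bl)$form, "quadratic")
  expect_error(demand_model("5+Y_LIN", st, baseline = NULL), "baseline")
})

test_that("stage selection keeps the five stages closest to the 55-80% band", {
  peak <- 20
  # 7 stages from 45% to 95% of peak
  frac <- seq(0.45, 0.95, length.out = 7)
  st <- stage_table(speed = seq(2, 5, length.out = 7), mr = frac * peak)
  sel <- select_stages_by_intensity(st, peak, n = 5)
  expect_equal(nrow(sel), 5)
  kept_frac <- sel$mr / peak
  # 45% (0.10 below band) and 95% (0.15 above) are the two farthest; the
  # tie-break keeps higher intensities when distances match
  expect_false(any(abs(kept_frac - 0.45) < 1e-9))
  expect_false(any(abs(kept_frac - 0.95) < 1e-9))
  expect_identical(select_stages_by_intensity(st[1:4, ], peak, n = 5),
                   st[1:4, ])
})

test_that("models serialize to JSON with coefficients and diagnostics", {
  m <- demand_model("5-Y_LIN", group_mean_stages(), group_mean_baseline())
  parsed <- jsonlite::fromJSON(model_to_json(m))
  expect_equal(parsed$form, "linear")
  expect_equal(parsed$coefficients[["slope"]],
               unname(m$coefficients[["slope"]]))
  expect_equal(parsed$n_stages_used, 5)
})
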