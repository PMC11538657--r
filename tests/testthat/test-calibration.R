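make_pulse_trace <- function(times, base, amp, t_meal, tp = 50) {
  tt <- times - t_meal
  pulse <- ifelse(tt > 0, (tt / tp)^3 * exp(3 * (1 - tt / tp)), 0)
  base + amp * pulse
}

test_that("two-point fit reproduces the hand-worked anchor arithmetic", {
  times <- 0:200
  E <- potential_trace(times, make_pulse_trace(times, 160, 60, 60))
  BG <- glucose_trace(times, make_pulse_trace(times, 90, 45, 60))
  cal <- fit_two_point(E, BG, meal_time = 60, smooth_window = 0)
  expect_equal(cal$m, 60 / 45, tolerance = 1e-12)       # 1.333 mV/(mg/dL)
  expect_equal(cal$dE_o, 60 / 45 * 90, tolerance = 1e-12)  # 120 mV
  expect_equal(cal$c, -120, tolerance = 1e-12)
  expect_equal(cal$E_o, 160)
  expect_equal(cal$BG_f, 90)
  expect_equal(cal$BG_max, 135)
})

test_that("noiseless synthetic trials invert to the generating slope exactly", {
  for (slope in c(0.2, 0.64, 1.34)) {
    p <- noiseless_profile(true_slope = slope, seed = 3)
    tr <- noiseless_trial(p)
    cal <- fit_two_point(tr$E, tr$bg, meal_time = p$meal_times[1],
                         smooth_window = 0)
    expect_equal(cal$m, slope, tolerance = 1e-12)
  }
})

test_that("printed-average generators are recovered self-consistently", {
  # m = 1.34 mV/(mg/dL) and c = -138 mV imply a fasting anchor of
  # BG_f = 138/1.34 ~ 103 mg/dL
  p <- noiseless_profile(true_slope = 1.34, fasting_bg = 138 / 1.34)
  tr <- noiseless_trial(p)
  cal <- fit_two_point(tr$E, tr$bg, meal_time = p$meal_times[1],
                       smooth_window = 0)
  expect_equal(cal$m, 1.34, tolerance = 1e-12)
  expect_equal(cal$c, -138, tolerance = 1e-12)
  expect_equal(cal$BG_f, 138 / 1.34, tolerance = 1e-12)
})

test_that("both calibration anchors hold to machine precision", {
  set.seed(11)
  for (i in 1:25) {
    E_o <- runif(1, 100, 300)
    dE_max <- runif(1, 5, 120)
    BG_f <- runif(1, 70, 130)
    BG_max <- BG_f + runif(1, 20, 200)
    cal <- calibration_params(E_o, dE_max, BG_f, BG_max)
    anchors <- potential_trace(c(0, 1), c(E_o, E_o + dE_max))
    sbg <- apply_calibration(anchors, cal)
    expect_equal(sbg$values[1], BG_f, tolerance = 1e-9)
    expect_equal(sbg$values[2], BG_max, tolerance = 1e-9)
  }
})

test_that("the worked line with the printed averages gives SBG ~ 152.99", {
  # m = 1.34, dE_o = 138 mV, E - E_o = 67 mV -> SBG = (67+138)/1.34
  cal <- calibration_params(E_o = 160, dE_max = 1.34 * (241 - 138 / 1.34),
                            BG_f = 138 / 1.34, BG_max = 241)
  expect_equal(cal$m, 1.34, tolerance = 1e-12)
  sbg <- apply_calibration(potential_trace(0, 160 + 67), cal)
  expect_equal(sbg$values, (67 + 138) / 1.34, tolerance = 1e-12)
  expect_equal(sbg$values, 152.99, tolerance = 1e-4)
})

test_that("SBG is strictly increasing in the potential", {
  cal <- calibration_params(160, 60, 90, 135)
  E <- potential_trace(0:100, seq(100, 300, length.out = 101))
  sbg <- suppressWarnings(apply_calibration(E, cal))
  expect_true(all(diff(sbg$values) > 0))
})

test_that("round-trip through fit and apply reproduces the sweat proxy", {
  p <- noiseless_profile(true_slope = 1.1, seed = 9)
  tr <- noiseless_trial(p)
  cal <- fit_two_point(tr$E, tr$bg, meal_time = p$meal_times[1],
                       smooth_window = 0)
  sbg <- apply_calibration(tr$E, cal)
  m <- mard(list(ref_bg = tr$sweat$values, est_sbg = sbg$values))
  expect_lt(m, 0.5)
})

test_that("degenerate and low-signal trials are rejected", {
  times <- 0:120
  flatE <- potential_trace(times, rep(160, 121))
  flatBG <- glucose_trace(times, rep(90, 121))
  risingE <- potential_trace(times, make_pulse_trace(times, 160, 60, 30))
  expect_error(fit_two_point(risingE, flatBG, meal_time = 30,
                             smooth_window = 0), "degenerate")
  risingBG <- glucose_trace(times, make_pulse_trace(times, 90, 45, 30))
  expect_error(fit_two_point(flatE, risingBG, meal_time = 30,
                             smooth_window = 0), "low-signal")
  expect_error(calibration_params(160, 60, BG_f = 120, BG_max = 100),
               "degenerate")
})

test_that("negative SBG estimates are clipped with a warning", {
  cal <- calibration_params(E_o = 160, dE_max = 60, BG_f = 90, BG_max = 135)
  E <- potential_trace(0:1, c(-500, 160))
  expect_warning(sbg <- apply_calibration(E, cal), "clipped")
  expect_equal(sbg$values[1], 0)
})

test_that("stability assessment measures relative drift of m and c", {
  cp <- function(dE, day) calibration_params(160, dE, 90, 135,
                                             fitted_on = day)
  same <- assess_stability(list(cp(60, 1), cp(60, 23), cp(60, 50)))
  expect_equal(same$drift_pct_m, 0)
  expect_true(same$pass)

  drifted <- assess_stability(list(cp(60, 1), cp(66, 23)), tol_pct = 5)
  expect_equal(drifted$drift_pct_m, 10, tolerance = 1e-12)
  expect_false(drifted$pass)

  expect_error(assess_stability(list(cp(60, 1))), "at least two")
  expect_error(assess_stability(list()), "at least two")
})

test_that("repeat-day protocol with a slowly drifting sensor stays stable", {
  p <- noiseless_profile(seed = 21)
  out <- repeat_day_stability(p, days = c(1, 23, 50),
                              drift_pct_per_day = 0.02, tol_pct = 10)
  expect_length(out$series, 3)
  expect_true(out$report$pass)
  expect_lt(out$report$drift_pct_m, 2)
})
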