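test_that("MARD matches hand arithmetic and elementwise oracle", {
  expect_equal(mard(list(ref_bg = c(100, 200), est_sbg = c(110, 180))), 10)
  expect_equal(mard(list(ref_bg = 100, est_sbg = 90)), 10)
  expect_equal(mard(list(ref_bg = c(90, 120), est_sbg = c(90, 120))), 0)
  expect_error(mard(list(ref_bg = c(100, 0), est_sbg = c(100, 10))),
               "positive")

  set.seed(4)
  ref <- runif(500, 40, 400)
  est <- ref * runif(500, 0.7, 1.3)
  oracle <- 0
  for (i in seq_along(ref)) oracle <- oracle + abs(ref[i] - est[i]) / ref[i]
  oracle <- oracle / length(ref) * 100
  expect_equal(mard(list(ref_bg = ref, est_sbg = est)), oracle,
               tolerance = 1e-12)
})

test_that("MARD is invariant under a common rescaling", {
  set.seed(8)
  ref <- runif(100, 50, 300)
  est <- ref + rnorm(100, 0, 15)
  base <- mard(list(ref_bg = ref, est_sbg = est))
  for (k in c(0.5, 2, 10))
    expect_equal(mard(list(ref_bg = k * ref, est_sbg = k * est)), base,
                 tolerance = 1e-12)
})

test_that("pairing interpolates the estimate at reference timestamps", {
  ref <- glucose_trace(c(0, 15, 30), c(100, 105, 110))
  est <- glucose_trace(c(0, 10, 20, 30), c(100, 100, 110, 110), kind = "SBG")
  pr <- pair_traces(ref, est)
  expect_equal(pr$est_sbg[2], 105)  # t=15 midway between 100 and 110
  expect_equal(pr$N, 3)

  same <- pair_traces(ref, ref)
  expect_equal(same$est_sbg, ref$values)

  late <- glucose_trace(c(100, 110), c(100, 100), kind = "SBG")
  expect_error(pair_traces(ref, late), "overlap")

  sparse <- glucose_trace(c(7.5, 22.5), c(100, 100), kind = "SBG")
  expect_error(pair_traces(ref, sparse, max_gap = 2), "max_gap")
})

test_that("identity pairs land in zone A on both grids", {
  refs <- seq(20, 540, by = 20)
  expect_true(all(error_grid_zone(refs, refs, "consensus_T1D") == "A"))
  expect_true(all(error_grid_zone(refs, refs, "clarke") == "A"))
  expect_error(error_grid_zone(-1, 100), "non-negative")
})

test_that("consensus-grid zones agree with a point-in-polygon oracle", {
  set.seed(12)
  n <- 10000
  ref <- runif(n, 0, 550)
  est <- runif(n, 0, 550)
  zones <- error_grid_zone(ref, est, "consensus_T1D")
  oracle <- vapply(seq_len(n),
                   function(i) parkes_zone_oracle(ref[i], est[i]),
                   character(1))
  expect_identical(zones, oracle)
})

test_that("frac_AB approaches 1 as estimate noise vanishes", {
  set.seed(3)
  ref <- runif(300, 80, 250)
  frac_ab <- function(sd) {
    est <- pmax(ref + rnorm(300, 0, sd), 0)
    z <- error_grid_zone(ref, est, "consensus_T1D")
    mean(z %in% c("A", "B"))
  }
  f <- vapply(c(150, 40, 5, 0), frac_ab, numeric(1))
  expect_true(all(diff(f) >= 0))
  expect_equal(f[4], 1)
})

test_that("lag estimator recovers a pure shift and the identity", {
  p <- subject_profile(noise_sd = 0)
  bg <- gen_bg_profile(p, 300)
  shifted <- blood_to_sweat(bg, 30, 0)
  lags <- lag_estimates(bg, shifted)
  expect_equal(lags$onset_lag, 30, tolerance = 1)
  expect_equal(lags$peak_lag, 30, tolerance = 1)

  same <- lag_estimates(bg, bg)
  expect_equal(same$onset_lag, 0)
  expect_equal(same$peak_lag, 0)

  flat <- glucose_trace(0:100, rep(100, 101))
  expect_warning(none <- lag_estimates(bg, flat), "no rise")
  expect_true(is.na(none$onset_lag))
})

test_that("first-order smoothing delays peaks more than thresholded onsets", {
  p <- subject_profile(noise_sd = 0, onset_lag = 25, smoothing_tau = 10)
  bg <- gen_bg_profile(p, 300)
  sw <- blood_to_sweat(bg, p$onset_lag, p$smoothing_tau)
  lags <- lag_estimates(bg, sw)
  expect_gt(lags$peak_lag, lags$onset_lag)
  expect_gte(lags$onset_lag, 25)
})

test_that("rate-stratified MARD matches hand-binned arithmetic", {
  pr <- structure(list(times = c(0, 10, 20, 30),
                       ref_bg = c(100, 110, 130, 130),
                       est_sbg = c(105, 110, 143, 156), N = 4L),
                  class = "paired_samples")
  # central-difference rates: 1, 1.5, 1, 0 mg/dL/min
  out <- rate_stratified_mard(pr, bin_edges = 1.25)
  expect_equal(out[["<1.25"]], mean(c(0.05, 0.10, 0.20)) * 100,
               tolerance = 1e-12)
  expect_equal(out[[">=1.25"]], 0)

  const <- structure(list(times = c(0, 15, 30), ref_bg = rep(100, 3),
                          est_sbg = c(90, 100, 110), N = 3L),
                     class = "paired_samples")
  out2 <- rate_stratified_mard(const, bin_edges = c(-1, 1))
  expect_equal(names(out2), "[-1,1)")

  expect_error(rate_stratified_mard(list(times = 0, ref_bg = 100,
                                         est_sbg = 100)), "at least two")
})

test_that("affine estimates with positive gain have Pearson r = 1", {
  set.seed(5)
  t <- seq(0, 240, by = 15)
  ref <- glucose_trace(t, 100 + 40 * sin(t / 40)^2)
  for (ab in list(c(1, 0), c(0.8, 20), c(2, -50))) {
    est <- glucose_trace(t, pmax(ab[1] * ref$values + ab[2], 0), kind = "SBG")
    rep <- suppressWarnings(accuracy_report(ref, est))
    expect_equal(rep$pearson_r, 1, tolerance = 1e-9)
  }
})

test_that("accuracy_report assembles consistent zone counts", {
  p <- subject_profile(seed = 6)
  trial <- simulate_trial(p)
  cal <- fit_two_point(trial$potential, trial$bg_ref,
                       meal_time = p$meal_times[1])
  sbg <- apply_calibration(trial$potential, cal)
  rep <- accuracy_report(trial$bg_ref, sbg)
  expect_equal(sum(unlist(rep$zone_counts)), rep$N)
  expect_gte(rep$frac_AB, 0)
  expect_lte(rep$frac_AB, 1)
  expect_lt(rep$mard, 25)
})
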