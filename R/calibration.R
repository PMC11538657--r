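#' Personalized two-point calibration parameters
#'
#' The calibration line maps sensor potential to sweat-based blood glucose
#' (SBG) through two anchors: the fasting state (potential `E_o`, glucose
#' `BG_f`) and the post-meal maximum (`E_o + dE_max`, `BG_max`). The slope
#' is `m = dE_max / (BG_max - BG_f)` in mV per (mg/dL) and the intercept of
#' the potential-vs-SBG line is `c = -dE_o`, with `dE_o = m * BG_f` so that
#' the line passes through the fasting point.
#'
#' @param subject_id character label.
#' @param site `"fingertip"` or `"forearm"`.
#' @param E_o fasting potential, mV.
#' @param dE_max maximum post-meal potential change, mV (> 0).
#' @param BG_f fasting blood glucose, mg/dL (> 0).
#' @param BG_max maximum blood glucose, mg/dL (> `BG_f`).
#' @param fitted_on date (or day index) the calibration was fitted.
#' @return An object of class `calibration_params` with derived fields
#'   `m`, `dE_o` and `c`.
#' @examples
#' cp <- calibration_params(E_o = 160, dE_max = 60, BG_f = 90, BG_max = 135)
#' cp$m            # 60/45
#' cp$c            # -m * BG_f
#' @export
calibration_params <- function(E_o, dE_max, BG_f, BG_max,
                               subject_id = "S01", site = "fingertip",
                               fitted_on = NA) {
  site <- match.arg(site, trace_sites)
  if (BG_max <= BG_f)
    stop("degenerate calibration: BG_max must exceed BG_f", call. = FALSE)
  if (dE_max <= 0)
    stop("degenerate calibration: dE_max must be positive", call. = FALSE)
  if (BG_f <= 0)
    stop("BG_f must be positive", call. = FALSE)
  m <- dE_max / (BG_max - BG_f)
  dE_o <- m * BG_f
  structure(list(subject_id = subject_id, site = site,
                 E_o = E_o, dE_max = dE_max, dE_o = dE_o,
                 BG_f = BG_f, BG_max = BG_max,
                 m = m, c = -dE_o, fitted_on = fitted_on),
            class = "calibration_params")
}

#' @exportS3Method base::print
print.calibration_params <- function(x, ...) {
  cat(sprintf(paste0("<calibration_params %s/%s> m = %.4g mV/(mg/dL), ",
                     "c = %.4g mV, E_o = %.4g mV, BG_f = %.4g, BG_max = %.4g mg/dL\n"),
              x$subject_id, x$site, x$m, x$c, x$E_o, x$BG_f, x$BG_max))
  invisible(x)
}

#' Fit the personalized two-point calibration
#'
#' Estimates the calibration anchors from one paired trial. The fasting
#' potential `E_o` is the mean potential over a pre-meal window (robust to
#' noise), `dE_max` the maximum of a lightly smoothed potential minus
#' `E_o`, `BG_f` the mean of the reference glucose samples in the fasting
#' window (or the first sample if none fall inside), and `BG_max` the
#' maximum observed reference sample, without interpolation.
#'
#' @param E a [potential_trace()] covering the trial.
#' @param BG a [glucose_trace()] of reference samples over the same span.
#' @param fasting_window length of the pre-meal averaging window, minutes.
#' @param meal_time meal timestamp, minutes; the fasting window is
#'   `[meal_time - fasting_window, meal_time]`. Defaults to the start of
#'   the potential trace plus `fasting_window`.
#' @param smooth_window moving-average window applied to `E` before taking
#'   its maximum, minutes; prevents single noise spikes from setting the
#'   anchor.
#' @param min_signal smallest acceptable `dE_max`, mV; below it the trial
#'   is rejected as low-signal.
#' @param subject_id,site,fitted_on metadata stored in the result.
#' @return A [calibration_params()] object.
#' @examples
#' p <- subject_profile(noise_sd = 0, drift_rate = 0, smoothing_tau = 0)
#' bg <- gen_bg_profile(p, 180)
#' sw <- blood_to_sweat(bg, p$onset_lag, 0)
#' E  <- gen_potential(sw, p)
#' fit_two_point(E, bg, meal_time = 60)$m   # recovers p$true_slope
#' @export
fit_two_point <- function(E, BG, fasting_window = 10, meal_time = NULL,
                          smooth_window = 5, min_signal = 5,
                          subject_id = "S01", site = E$site,
                          fitted_on = NA) {
  stopifnot(inherits(E, "potential_trace"), inherits(BG, "glucose_trace"),
            fasting_window > 0)
  if (is.null(meal_time)) meal_time <- E$times[1L] + fasting_window
  w0 <- meal_time - fasting_window
  in_win <- E$times >= w0 & E$times <= meal_time
  if (!any(in_win))
    stop("no potential samples in the fasting window", call. = FALSE)
  E_o <- mean(E$values[in_win])

  E_smooth <- moving_average(E$values, E$times, smooth_window)
  dE_max <- max(E_smooth[E$times >= meal_time]) - E_o
  if (dE_max < min_signal)
    stop(sprintf("low-signal trial: dE_max = %.3g mV < %g mV", dE_max,
                 min_signal), call. = FALSE)

  bg_win <- BG$times >= w0 & BG$times <= meal_time
  BG_f <- if (any(bg_win)) mean(BG$values[bg_win]) else BG$values[1L]
  BG_max <- max(BG$values)
  if (BG_max <= BG_f)
    stop("degenerate calibration: BG never rose above its fasting value",
         call. = FALSE)
  calibration_params(E_o = E_o, dE_max = dE_max, BG_f = BG_f,
                     BG_max = BG_max, subject_id = subject_id, site = site,
                     fitted_on = fitted_on)
}

# centered moving average over a window of `width` time units;
# width <= 0 or a single sample returns the input unchanged
moving_average <- function(values, times, width) {
  if (width <= 0 || length(values) < 2L) return(values)
  half <- width / 2
  vapply(seq_along(values), function(i) {
    sel <- abs(times - times[i]) <= half
    mean(values[sel])
  }, numeric(1))
}

#' Convert a potential trace to sweat-based blood glucose
#'
#' Applies the two-point calibration line:
#' \deqn{SBG(t) = (E(t) - E_o + \Delta E_o) (BG_{max} - BG_f) / \Delta E_{max}}
#' so that `SBG(E_o) = BG_f` and `SBG(E_o + dE_max) = BG_max` exactly.
#' Negative estimates (possible when the potential drops far below the
#' fasting level) are clipped at 0 with a warning.
#'
#' @param E a [potential_trace()].
#' @param params a [calibration_params()].
#' @return A [glucose_trace()] of kind `"SBG"` on the same time grid.
#' @export
apply_calibration <- function(E, params) {
  stopifnot(inherits(E, "potential_trace"),
            inherits(params, "calibration_params"))
  if (params$dE_max == 0)
    stop("dE_max = 0: calibration line is degenerate", call. = FALSE)
  sbg <- (E$values - params$E_o + params$dE_o) *
    (params$BG_max - params$BG_f) / params$dE_max
  if (any(sbg < 0)) {
    warning(sprintf("%d SBG estimate(s) below 0 mg/dL clipped to 0",
                    sum(sbg < 0)), call. = FALSE)
    sbg <- pmax(sbg, 0)
  }
  glucose_trace(E$times, sbg, kind = "SBG")
}

#' Assess the long-term stability of repeated calibrations
#'
#' Re-fitting the calibration on different days should return nearly the
#' same slope and intercept if the subject's sweat-glucose response is
#' stable; that stability is what justifies reusing day-1 parameters
#' without repeated blood calibration. Drift is measured as the maximum
#' relative deviation of `m` and `c` from their first-day values.
#'
#' @param series a list of [calibration_params()] fitted on different days,
#'   ordered by `fitted_on`.
#' @param tol_pct pass/fail threshold on both drifts, percent.
#' @return A list with `drift_pct_m`, `drift_pct_c`, `pass`, `n_days`.
#' @examples
#' cp1 <- calibration_params(160, 60, 90, 135, fitted_on = 1)
#' cp2 <- calibration_params(162, 66, 90, 135, fitted_on = 23)
#' assess_stability(list(cp1, cp2), tol_pct = 15)
#' @export
assess_stability <- function(series, tol_pct = 10) {
  if (!is.list(series) || length(series) < 2L)
    stop("stability assessment needs at least two calibrations",
         call. = FALSE)
  stopifnot(all(vapply(series, inherits, logical(1), "calibration_params")))
  m <- vapply(series, `[[`, numeric(1), "m")
  cc <- vapply(series, `[[`, numeric(1), "c")
  drift_m <- max(abs(m - m[1L]) / abs(m[1L])) * 100
  drift_c <- max(abs(cc - cc[1L]) / abs(cc[1L])) * 100
  list(drift_pct_m = drift_m, drift_pct_c = drift_c,
       pass = drift_m <= tol_pct && drift_c <= tol_pct,
       n_days = length(series))
}
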