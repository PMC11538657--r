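#' Synthetic subject profile
#'
#' Bundles the generative parameters of one synthetic subject: fasting
#' glucose, meal schedule and excursion amplitudes, blood-to-sweat lag,
#' the linear transduction of sweat glucose into sensor potential, and the
#' noise/drift model of the potentiometric readout.
#'
#' Defaults describe a healthy fingertip subject: fasting glucose near
#' 103 mg/dL, one meal 60 min into the trial with a 42 mg/dL excursion,
#' a 30-min blood-to-sweat onset lag with mild first-order smoothing, and
#' a transduction slope of 1.34 mV/(mg/dL). Cohort/site presets rescale
#' these: diabetic subjects get 150 mg/dL excursions from an elevated
#' fasting baseline; forearm sites get a much smaller slope (0.20
#' mV/(mg/dL)), reflecting the lower sweat-gland density there.
#'
#' @param subject_id character label.
#' @param cohort `"healthy"` or `"diabetic"`.
#' @param site `"fingertip"` or `"forearm"`.
#' @param fasting_bg fasting blood glucose, mg/dL; must be positive.
#' @param meal_times minutes at which meals are consumed; strictly increasing.
#' @param meal_amplitudes peak blood-glucose excursion of each meal, mg/dL.
#' @param onset_lag blood-to-sweat onset delay, minutes (>= 0).
#' @param peak_time time from meal to blood-glucose peak, minutes.
#' @param smoothing_tau first-order blood-to-sweat smoothing constant, minutes.
#' @param true_slope transduction slope, mV per (mg/dL); must be positive.
#' @param true_intercept additive potential offset, mV.
#' @param noise_sd Gaussian sensor noise SD, mV.
#' @param drift_rate linear baseline drift, mV per hour.
#' @param cgm_lag blood-to-interstitial lag of the reference CGM, minutes.
#' @param seed integer seed from which all of the subject's random draws flow.
#' @return An object of class `subject_profile`.
#' @examples
#' p <- subject_profile(seed = 1)
#' p$true_slope
#' @export
subject_profile <- function(subject_id = "S01",
                            cohort = c("healthy", "diabetic"),
                            site = c("fingertip", "forearm"),
                            fasting_bg = NULL,
                            meal_times = 60,
                            meal_amplitudes = NULL,
                            onset_lag = 30,
                            peak_time = 50,
                            smoothing_tau = 5,
                            true_slope = NULL,
                            true_intercept = 20,
                            noise_sd = 1,
                            drift_rate = 0.5,
                            cgm_lag = 7,
                            seed = 1L) {
  cohort <- match.arg(cohort)
  site <- match.arg(site)
  if (is.null(fasting_bg))
    fasting_bg <- if (cohort == "healthy") 103 else 140
  if (is.null(meal_amplitudes))
    meal_amplitudes <- rep(if (cohort == "healthy") 42 else 150,
                           length(meal_times))
  if (is.null(true_slope))
    true_slope <- if (site == "fingertip") {
      if (cohort == "healthy") 1.34 else 0.64
    } else {
      if (cohort == "healthy") 0.20 else 0.36
    }
  stopifnot(fasting_bg > 0, onset_lag >= 0, smoothing_tau >= 0,
            true_slope > 0, peak_time > 0, noise_sd >= 0,
            length(meal_amplitudes) == length(meal_times))
  if (length(meal_times) > 1 && any(diff(meal_times) <= 0))
    stop("meal_times must be strictly increasing", call. = FALSE)
  structure(list(subject_id = subject_id, cohort = cohort, site = site,
                 fasting_bg = fasting_bg, meal_times = meal_times,
                 meal_amplitudes = meal_amplitudes, onset_lag = onset_lag,
                 peak_time = peak_time, smoothing_tau = smoothing_tau,
                 true_slope = true_slope, true_intercept = true_intercept,
                 noise_sd = noise_sd, drift_rate = drift_rate,
                 cgm_lag = cgm_lag, seed = as.integer(seed)),
            class = "subject_profile")
}

#' @exportS3Method base::print
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile %s> %s/%s, fasting %g mg/dL, %d meal(s), slope %g mV/(mg/dL), seed %d\n",
              x$subject_id, x$cohort, x$site, x$fasting_bg,
              length(x$meal_times), x$true_slope, x$seed))
  invisible(x)
}
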