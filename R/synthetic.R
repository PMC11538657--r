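#' Generate a blood-glucose profile for a synthetic subject
#'
#' Starts at the subject's fasting glucose and superimposes one smooth
#' unimodal excursion per meal. Each excursion is a gamma-variate pulse
#' \eqn{g(t) = (t/t_p)^k \exp(k (1 - t/t_p))}, normalized to peak exactly at
#' the configured amplitude `peak_time` minutes after the meal, the standard
#' pharmacodynamic response shape. Meals scheduled beyond the trial duration
#' are skipped with a warning.
#'
#' @param profile a [subject_profile()].
#' @param duration trial length, minutes (> 0).
#' @param step sampling interval, minutes (> 0).
#' @return A [glucose_trace()] of kind `"BG_fingerstick"` on the regular
#'   grid `seq(0, duration, by = step)`.
#' @examples
#' p <- subject_profile(meal_times = 60, meal_amplitudes = 42)
#' bg <- gen_bg_profile(p, duration = 180, step = 1)
#' max(bg$values) - p$fasting_bg   # ~42
#' @export
gen_bg_profile <- function(profile, duration, step = 1) {
  stopifnot(inherits(profile, "subject_profile"), duration > 0, step > 0)
  times <- seq(0, duration, by = step)
  values <- rep(profile$fasting_bg, length(times))
  k <- 3  # gamma-variate shape; rise ~ t^3
  for (j in seq_along(profile$meal_times)) {
    t_meal <- profile$meal_times[j]
    if (t_meal > duration) {
      warning(sprintf("meal at %g min is beyond trial duration %g min; ignored",
                      t_meal, duration), call. = FALSE)
      next
    }
    tt <- times - t_meal
    pulse <- ifelse(tt > 0,
                    (tt / profile$peak_time)^k *
                      exp(k * (1 - tt / profile$peak_time)),
                    0)
    values <- values + profile$meal_amplitudes[j] * pulse
  }
  glucose_trace(times, values, kind = "BG_fingerstick")
}

#' Map a blood-glucose trace to its sweat-glucose proxy
#'
#' Models blood-to-sweat partitioning as a pure onset delay followed by a
#' first-order low-pass filter: the minimal model that reproduces both a
#' delayed onset and a further-delayed, slightly attenuated peak. The filter
#' is integrated exactly for piecewise-linear input (exponential
#' integrator), so the asymptotic lag of a ramp response equals
#' `onset_lag + smoothing_tau` independent of the sampling step.
#'
#' @param bg a [glucose_trace()] (any kind) on a strictly increasing grid.
#' @param onset_lag pure delay, minutes (>= 0).
#' @param smoothing_tau first-order time constant, minutes (>= 0; 0 disables
#'   the filter).
#' @return A [glucose_trace()] of kind `"sweat_proxy"` on the same time grid.
#' @examples
#' p <- subject_profile()
#' bg <- gen_bg_profile(p, 180)
#' sw <- blood_to_sweat(bg, onset_lag = 30, smoothing_tau = 5)
#' @export
blood_to_sweat <- function(bg, onset_lag, smoothing_tau = 0) {
  stopifnot(inherits(bg, "glucose_trace"))
  if (onset_lag < 0) stop("onset_lag must be >= 0", call. = FALSE)
  if (smoothing_tau < 0) stop("smoothing_tau must be >= 0", call. = FALSE)
  times <- bg$times
  # delayed input, held at the initial value before signal onset
  x <- trace_at(bg, times - onset_lag, rule = 2)
  if (smoothing_tau == 0 || length(times) == 1L) {
    y <- x
  } else {
    y <- numeric(length(x))
    y[1L] <- x[1L]
    for (i in 2:length(x)) {
      dt <- times[i] - times[i - 1L]
      s <- (x[i] - x[i - 1L]) / dt
      e <- exp(-dt / smoothing_tau)
      # exact solution of tau y' = x - y over a linear segment of slope s
      y[i] <- x[i] - s * smoothing_tau +
        (y[i - 1L] - x[i - 1L] + s * smoothing_tau) * e
    }
  }
  glucose_trace(times, pmax(y, 0), kind = "sweat_proxy")
}

#' Generate the sensor potential from a sweat-glucose trace
#'
#' Linear transduction of the sweat-glucose proxy into the potential across
#' the sensor's external load: slope times concentration, plus a fixed
#' offset, a linear baseline drift, and additive Gaussian noise. All random
#' draws flow from the profile seed, so identical inputs give bitwise
#' identical traces.
#'
#' @param sweat a [glucose_trace()] (normally kind `"sweat_proxy"`).
#' @param profile a [subject_profile()] supplying `true_slope` (mV per
#'   mg/dL), `true_intercept` (mV), `drift_rate` (mV/hour), `noise_sd` (mV),
#'   `site` and `seed`.
#' @return A [potential_trace()] on the same time grid.
#' @export
gen_potential <- function(sweat, profile) {
  stopifnot(inherits(sweat, "glucose_trace"),
            inherits(profile, "subject_profile"))
  clean <- profile$true_slope * sweat$values + profile$true_intercept +
    profile$drift_rate * sweat$times / 60
  noise <- if (profile$noise_sd > 0) {
    withr::with_seed(profile$seed,
                     stats::rnorm(length(clean), 0, profile$noise_sd))
  } else {
    0
  }
  potential_trace(sweat$times, clean + noise, site = profile$site)
}

#' Generate a CGM readout from a blood-glucose trace
#'
#' A commercial CGM measures interstitial glucose, which tracks blood
#' glucose with a short (~5-10 min) lag. The model resamples the blood
#' trace at the CGM cadence, shifts it by the configured lag and adds
#' Gaussian noise.
#'
#' @param bg a [glucose_trace()].
#' @param cgm_lag blood-to-interstitial lag, minutes (>= 0).
#' @param noise_sd Gaussian noise SD, mg/dL.
#' @param seed integer seed.
#' @param cadence CGM sampling interval, minutes (default 5).
#' @return A [glucose_trace()] of kind `"CGM"`.
#' @export
gen_cgm <- function(bg, cgm_lag = 7, noise_sd = 2, seed = 1L, cadence = 5) {
  stopifnot(inherits(bg, "glucose_trace"), cadence > 0)
  if (cgm_lag < 0) stop("cgm_lag must be >= 0", call. = FALSE)
  t0 <- bg$times[1L]
  t1 <- bg$times[length(bg$times)]
  times <- seq(t0, t1, by = cadence)
  values <- trace_at(bg, times - cgm_lag, rule = 2)
  if (noise_sd > 0)
    values <- values + withr::with_seed(
      seed, stats::rnorm(length(values), 0, noise_sd))
  glucose_trace(times, pmax(values, 0), kind = "CGM")
}

#' Generate a sweat-rate trace
#'
#' Osmotically extracted sweat shows small fluctuations (~2 nL/min/cm^2)
#' around a steady baseline, whereas natural perspiration rises from ~10
#' nL/min/cm^2 pre-meal to ~40-45 nL/min/cm^2 post-meal. Meal responses use
#' the same gamma-variate pulse as the glucose generator.
#'
#' @param profile a [subject_profile()] (meal schedule and seed).
#' @param duration trial length, minutes.
#' @param osmotic logical; `TRUE` emulates the osmotic hydrogel regime,
#'   `FALSE` natural perspiration.
#' @param baseline,fluctuation baseline level and meal-excursion amplitude,
#'   nL min^-1 cm^-2; defaults depend on `osmotic` (35 and 2 for the
#'   osmotic regime, 10 and 32 for natural perspiration).
#' @param noise_sd Gaussian jitter SD, nL min^-1 cm^-2 (default 0).
#' @param step sampling interval, minutes.
#' @return A [sweat_rate_trace()].
#' @export
gen_sweat_rate <- function(profile, duration, osmotic = TRUE,
                           baseline = if (osmotic) 35 else 10,
                           fluctuation = if (osmotic) 2 else 32,
                           noise_sd = 0, step = 1) {
  stopifnot(inherits(profile, "subject_profile"), duration > 0, step > 0)
  times <- seq(0, duration, by = step)
  values <- rep(baseline, length(times))
  k <- 3
  for (j in seq_along(profile$meal_times)) {
    t_meal <- profile$meal_times[j]
    if (t_meal > duration) next
    tt <- times - t_meal
    pulse <- ifelse(tt > 0,
                    (tt / profile$peak_time)^k *
                      exp(k * (1 - tt / profile$peak_time)),
                    0)
    values <- values + fluctuation * pulse
  }
  if (noise_sd > 0)
    values <- values + withr::with_seed(
      profile$seed + 1L, stats::rnorm(length(values), 0, noise_sd))
  sweat_rate_trace(times, pmax(values, 0))
}
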