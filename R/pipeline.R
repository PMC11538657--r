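#' Simulate one complete synthetic trial
#'
#' Runs the full generative chain for one subject: blood glucose profile,
#' blood-to-sweat transfer, sensor potential, CGM readout and sweat rate,
#' all driven by the profile's seed. This mirrors the on-body protocol:
#' record the fasting baseline, consume a meal, then follow sweat, blood
#' and CGM glucose over the next hours.
#'
#' @param profile a [subject_profile()].
#' @param duration trial length, minutes.
#' @param step sensor sampling interval, minutes.
#' @param bg_step reference fingerstick interval, minutes (default 15,
#'   the usual fingerstick cadence).
#' @param osmotic logical, sweat-extraction regime for the sweat-rate
#'   trace.
#' @return A list of class `trial_bundle`: `profile`, `bg` (dense truth),
#'   `bg_ref` (fingerstick-cadence reference), `sweat`, `potential`,
#'   `cgm`, `sweat_rate`, `provenance`.
#' @export
simulate_trial <- function(profile, duration = 240, step = 1,
                           bg_step = 15, osmotic = TRUE) {
  stopifnot(inherits(profile, "subject_profile"))
  bg <- gen_bg_profile(profile, duration, step)
  sweat <- blood_to_sweat(bg, profile$onset_lag, profile$smoothing_tau)
  pot <- gen_potential(sweat, profile)
  cgm <- gen_cgm(bg, cgm_lag = profile$cgm_lag, seed = profile$seed + 2L)
  sr <- gen_sweat_rate(profile, duration, osmotic = osmotic)
  ref_t <- seq(0, duration, by = bg_step)
  bg_ref <- glucose_trace(ref_t, trace_at(bg, ref_t),
                          kind = "BG_fingerstick")
  structure(list(profile = profile, bg = bg, bg_ref = bg_ref,
                 sweat = sweat, potential = pot, cgm = cgm,
                 sweat_rate = sr,
                 provenance = list(hash = config_hash(unclass(profile)),
                                   seed = profile$seed)),
            class = "trial_bundle")
}

#' Default pipeline configuration
#'
#' @param n_subjects cohort size.
#' @param cohort `"healthy"` or `"diabetic"`.
#' @param site `"fingertip"` or `"forearm"`.
#' @param duration,step,bg_step trial timing, minutes.
#' @param seed master seed; subject seeds are derived from it.
#' @param profile_args named list of [subject_profile()] overrides applied
#'   to every subject.
#' @param grid error grid for evaluation.
#' @return A named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(n_subjects = 20, cohort = "healthy",
                            site = "fingertip", duration = 240, step = 1,
                            bg_step = 15, seed = 1L,
                            profile_args = list(),
                            grid = "consensus_T1D") {
  list(n_subjects = n_subjects, cohort = cohort, site = site,
       duration = duration, step = step, bg_step = bg_step,
       seed = as.integer(seed), profile_args = profile_args, grid = grid)
}

#' Run the full simulate-calibrate-estimate-evaluate pipeline
#'
#' For each synthetic subject: generate a trial, fit the two-point
#' calibration on its potential and fingerstick reference, convert the
#' potential to SBG, and evaluate SBG against the reference. Per-subject
#' accuracy reports are pooled into cohort-level MARD, Pearson r and
#' error-grid zone fractions. A subject whose calibration fails (e.g.
#' degenerate trial) is logged and skipped; the others continue. Fully
#' reproducible: the same config and seed give bitwise-identical output.
#'
#' @param config a [pipeline_config()] list.
#' @param out_dir optional directory; when given, per-subject trial CSVs,
#'   calibration JSONs and the pooled report JSON are written under it.
#' @return A list of class `pipeline_result`: `per_subject` (accuracy
#'   reports), `pooled` (pooled MARD, r, zone counts, frac_AB, N),
#'   `params` (fitted calibrations), `failures`, `config`, `config_hash`.
#' @examples
#' res <- run_pipeline(pipeline_config(n_subjects = 2, seed = 7))
#' res$pooled$mard
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  hash <- config_hash(config)
  reports <- list(); params <- list(); failures <- character(0)
  all_ref <- numeric(0); all_est <- numeric(0)
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    res <- tryCatch({
      prof <- do.call(subject_profile, c(
        list(subject_id = sid, cohort = config$cohort, site = config$site,
             seed = config$seed + s),
        config$profile_args))
      trial <- simulate_trial(prof, duration = config$duration,
                              step = config$step, bg_step = config$bg_step)
      cal <- fit_two_point(trial$potential, trial$bg_ref,
                           meal_time = prof$meal_times[1L],
                           subject_id = sid, fitted_on = 1)
      sbg <- apply_calibration(trial$potential, cal)
      rep <- accuracy_report(trial$bg_ref, sbg, grid = config$grid)
      if (!is.null(out_dir)) {
        sdir <- file.path(out_dir, sid)
        write_trial(trial, sdir)
        write_calibration(cal, file.path(sdir, "params.json"))
        write_trace(sbg, file.path(sdir, "sbg.csv"))
      }
      pairs <- pair_traces(trial$bg_ref, sbg)
      list(cal = cal, rep = rep, pairs = pairs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(sid, ": ", conditionMessage(res)))
      message("subject ", sid, " skipped: ", conditionMessage(res))
      next
    }
    reports[[sid]] <- res$rep
    params[[sid]] <- res$cal
    all_ref <- c(all_ref, res$pairs$ref_bg)
    all_est <- c(all_est, res$pairs$est_sbg)
  }
  if (!length(reports))
    stop("all subjects failed; nothing to pool", call. = FALSE)
  zones <- error_grid_zone(all_ref, all_est, grid = config$grid)
  counts <- table(factor(zones, levels = c("A", "B", "C", "D", "E")))
  pooled <- list(
    mard = mard(list(ref_bg = all_ref, est_sbg = all_est)),
    pearson_r = stats::cor(all_ref, all_est),
    zone_counts = as.list(counts),
    frac_AB = unname((counts[["A"]] + counts[["B"]]) / length(all_ref)),
    N = length(all_ref))
  out <- structure(list(per_subject = reports, pooled = pooled,
                        params = params, failures = failures,
                        config = config, config_hash = hash),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- list(config_hash = hash, pooled = pooled,
                   per_subject = lapply(reports, unclass),
                   failures = failures)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result %s> %d/%d subjects, pooled MARD = %.2f%%, r = %.3f, A+B = %.1f%%\n",
              x$config_hash, length(x$per_subject), x$config$n_subjects,
              x$pooled$mard, x$pooled$pearson_r, 100 * x$pooled$frac_AB))
  invisible(x)
}

#' Repeat-day calibration stability experiment
#'
#' Mirrors the multi-day wear protocol: the subject is calibrated on day
#' 1, then re-measured on later days with the generator's slope and
#' intercept drifted by a configured percentage per re-measurement, and
#' the calibration re-fitted each day. The resulting series feeds
#' [assess_stability()].
#'
#' @param profile day-1 [subject_profile()].
#' @param days numeric vector of day indices (e.g. `c(1, 23, 50)`).
#' @param drift_pct_per_day relative drift of the generating slope per
#'   day, percent.
#' @param tol_pct stability tolerance handed to [assess_stability()].
#' @param duration,step,bg_step trial timing, minutes.
#' @return List with the fitted `series` and the stability `report`.
#' @export
repeat_day_stability <- function(profile, days = c(1, 23, 50),
                                 drift_pct_per_day = 0.02, tol_pct = 10,
                                 duration = 240, step = 1, bg_step = 15) {
  stopifnot(length(days) >= 2L)
  series <- vector("list", length(days))
  for (i in seq_along(days)) {
    d <- days[i]
    p <- profile
    p$true_slope <- profile$true_slope *
      (1 + drift_pct_per_day / 100 * (d - days[1L]))
    p$seed <- profile$seed + 100L * i
    trial <- simulate_trial(p, duration = duration, step = step,
                            bg_step = bg_step)
    series[[i]] <- fit_two_point(trial$potential, trial$bg_ref,
                                 meal_time = p$meal_times[1L],
                                 subject_id = profile$subject_id,
                                 fitted_on = d)
  }
  list(series = series, report = assess_stability(series, tol_pct = tol_pct))
}
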