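#' Pair a reference glucose trace with an estimate trace
#'
#' For every reference sample inside the overlap, the (denser) estimate is
#' linearly interpolated at the reference timestamp; this matches the
#' 15-min fingerstick cadence against a 1-min sensor estimate. Reference
#' samples whose nearest estimate sample is further away than `max_gap`
#' are dropped and counted.
#'
#' @param ref reference [glucose_trace()] (e.g. fingerstick BG).
#' @param est estimate [glucose_trace()] (e.g. SBG).
#' @param max_gap largest tolerated distance to the nearest estimate
#'   sample, minutes.
#' @return An object of class `paired_samples`: `times`, `ref_bg`,
#'   `est_sbg`, `N`, `n_dropped`.
#' @examples
#' r <- glucose_trace(c(0, 15), c(100, 110))
#' e <- glucose_trace(c(10, 20), c(100, 110), kind = "SBG")
#' pair_traces(r, e)$est_sbg
#' @export
pair_traces <- function(ref, est, max_gap = 5) {
  stopifnot(inherits(ref, "glucose_trace"), inherits(est, "glucose_trace"))
  lo <- max(ref$times[1L], est$times[1L])
  hi <- min(ref$times[length(ref$times)], est$times[length(est$times)])
  if (lo > hi) stop("traces do not overlap in time", call. = FALSE)
  keep <- ref$times >= lo & ref$times <= hi
  times <- ref$times[keep]
  gap <- vapply(times, function(t) min(abs(est$times - t)), numeric(1))
  ok <- gap <= max_gap
  n_dropped <- sum(!ok) + sum(!keep)
  times <- times[ok]
  if (!length(times))
    stop("no reference sample within max_gap of the estimate trace",
         call. = FALSE)
  structure(list(times = times,
                 ref_bg = ref$values[keep][ok],
                 est_sbg = trace_at(est, times),
                 N = length(times), n_dropped = n_dropped),
            class = "paired_samples")
}

#' Mean absolute relative difference (MARD)
#'
#' The standard accuracy metric of continuous glucose monitoring:
#' \deqn{MARD = \frac{100}{N} \sum_{i=1}^{N}
#'   \frac{|BG_i - SBG_i|}{BG_i}}
#' in percent, with the reference in the denominator.
#'
#' @param pairs a `paired_samples` object from [pair_traces()], or a list
#'   with numeric `ref_bg` and `est_sbg`.
#' @return MARD in percent.
#' @examples
#' mard(list(ref_bg = c(100, 200), est_sbg = c(110, 180)))  # 10
#' @export
mard <- function(pairs) {
  ref <- pairs$ref_bg; est <- pairs$est_sbg
  stopifnot(length(ref) == length(est), length(ref) >= 1L)
  if (any(ref <= 0))
    stop("MARD undefined: reference glucose must be positive", call. = FALSE)
  mean(abs(ref - est) / ref) * 100
}

#' Error-grid zone assignment
#'
#' Assigns each (reference, estimate) pair to a clinical-risk zone A-E of
#' either the Parkes consensus error grid for type-1 diabetes (vertices
#' from [parkes_t1d_vertices()]) or the Clarke error grid. Points exactly
#' on a boundary are assigned to the lower-risk zone. Zones A and B are
#' considered clinically acceptable.
#'
#' @param ref reference glucose, mg/dL (vector).
#' @param est estimated glucose, mg/dL (vector, recycled against `ref`).
#' @param grid `"consensus_T1D"` (Parkes) or `"clarke"`.
#' @return Character vector of zones `"A"`..`"E"`.
#' @examples
#' error_grid_zone(100, 100)              # "A"
#' error_grid_zone(100, 210)              # above the A and B bands
#' @export
error_grid_zone <- function(ref, est, grid = c("consensus_T1D", "clarke")) {
  grid <- match.arg(grid)
  n <- max(length(ref), length(est))
  ref <- rep_len(as.numeric(ref), n); est <- rep_len(as.numeric(est), n)
  if (any(ref < 0) || any(est < 0))
    stop("glucose values must be non-negative", call. = FALSE)
  if (grid == "consensus_T1D") parkes_zone_t1d(ref, est)
  else clarke_zone(ref, est)
}

parkes_zone_t1d <- function(ref, est) {
  v <- parkes_t1d_vertices()
  up_ab <- pw_boundary(v$AB_upper)(ref)
  up_bc <- pw_boundary(v$BC_upper)(ref)
  up_cd <- pw_boundary(v$CD_upper)(ref)
  up_de <- pw_boundary(v$DE_upper)(ref)
  # lower boundaries start with a vertical segment: below the first vertex
  # the zone reaches est = 0
  low_of <- function(verts) {
    f <- pw_boundary(verts[-1L, , drop = FALSE])
    function(x) ifelse(x <= verts[1L, 1L], -Inf, f(x))
  }
  lo_ab <- low_of(v$AB_lower)(ref)
  lo_bc <- low_of(v$BC_lower)(ref)
  lo_cd <- low_of(v$CD_lower)(ref)
  zone <- rep("E", length(ref))
  zone[est <= up_de] <- "D"           # no E zone below the identity line
  zone[est <= up_cd & est >= lo_cd] <- "C"
  zone[est <= up_bc & est >= lo_bc] <- "B"
  zone[est <= up_ab & est >= lo_ab] <- "A"
  zone
}

clarke_zone <- function(ref, est) {
  zone <- rep("B", length(ref))
  d <- (ref >= 240 & est >= 70 & est <= 180) |
    (ref <= 70 & est >= 70 & est <= 180)
  zone[d] <- "D"
  cc <- (ref >= 70 & ref <= 290 & est >= ref + 110) |
    (ref >= 130 & ref <= 180 & est <= (7 / 5) * ref - 182)
  zone[cc] <- "C"
  e <- (ref >= 180 & est <= 70) | (ref <= 70 & est >= 180)
  zone[e] <- "E"
  a <- (ref <= 70 & est <= 70) | (est <= 1.2 * ref & est >= 0.8 * ref)
  zone[a] <- "A"
  zone
}

#' Onset and peak lag between two glucose traces
#'
#' Both traces are lightly smoothed; the onset of each is the first time
#' it exceeds its baseline plus `onset_frac` of its net excursion and
#' stays above for a dwell window. The onset lag is the difference of the
#' two onsets, the peak lag the difference of the two maxima times.
#'
#' @param ref,est [glucose_trace()] objects (or any trace with `times` and
#'   `values`).
#' @param onset_frac fraction of the net excursion defining onset
#'   (default 0.1).
#' @param smooth moving-average smoothing window, minutes.
#' @param dwell time the trace must stay above threshold, minutes.
#' @param baseline_window initial window used as baseline, minutes.
#' @return List with `onset_lag`, `peak_lag` (minutes, positive when the
#'   estimate lags the reference), and per-trace onsets/peaks. `NA` with a
#'   warning if either trace shows no rise.
#' @examples
#' p <- subject_profile(noise_sd = 0)
#' bg <- gen_bg_profile(p, 240)
#' sw <- blood_to_sweat(bg, 30, 0)
#' lag_estimates(bg, sw)$onset_lag    # ~30
#' @export
lag_estimates <- function(ref, est, onset_frac = 0.1, smooth = 5,
                          dwell = 5, baseline_window = 10) {
  one <- function(tr) {
    v <- moving_average(tr$values, tr$times, smooth)
    t <- tr$times
    base <- mean(v[t <= t[1L] + baseline_window])
    pk <- max(v)
    if (pk <= base) return(list(onset = NA_real_, peak = NA_real_))
    thr <- base + onset_frac * (pk - base)
    above <- v >= thr
    onset <- NA_real_
    for (i in which(above)) {
      horizon <- t >= t[i] & t <= t[i] + dwell
      if (all(above[horizon])) { onset <- t[i]; break }
    }
    list(onset = onset, peak = t[which.max(v)])
  }
  r <- one(ref); e <- one(est)
  if (is.na(r$onset) || is.na(e$onset)) {
    warning("no rise detected in one of the traces; lags are NA",
            call. = FALSE)
    return(list(onset_lag = NA_real_, peak_lag = NA_real_,
                ref_onset = r$onset, est_onset = e$onset,
                ref_peak = r$peak, est_peak = e$peak))
  }
  list(onset_lag = e$onset - r$onset, peak_lag = e$peak - r$peak,
       ref_onset = r$onset, est_onset = e$onset,
       ref_peak = r$peak, est_peak = e$peak)
}

#' MARD stratified by reference rate of change
#'
#' Central-difference rate of change of the reference at each pair,
#' binned by `bin_edges`; MARD is reported per bin. Accuracy of sweat
#' estimates typically degrades when blood glucose changes rapidly,
#' because of the blood-to-sweat lag.
#'
#' @param pairs a `paired_samples` object with at least two samples.
#' @param bin_edges increasing numeric vector of bin edges, mg/dL/min;
#'   rates outside the outer edges fall into open-ended end bins.
#' @return Named list mapping bin label to MARD (percent); empty bins are
#'   absent.
#' @export
rate_stratified_mard <- function(pairs, bin_edges = c(-2, -1, 1, 2)) {
  t <- pairs$times; ref <- pairs$ref_bg; est <- pairs$est_sbg
  if (length(t) < 2L)
    stop("need at least two reference samples to form rates", call. = FALSE)
  n <- length(t)
  rate <- numeric(n)
  rate[1L] <- (ref[2L] - ref[1L]) / (t[2L] - t[1L])
  rate[n] <- (ref[n] - ref[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L)
    rate[2:(n - 1L)] <- (ref[3:n] - ref[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  edges <- sort(bin_edges)
  bin <- findInterval(rate, edges)
  labels <- c(paste0("<", edges[1L]),
              if (length(edges) > 1L)
                paste0("[", edges[-length(edges)], ",", edges[-1L], ")"),
              paste0(">=", edges[length(edges)]))
  out <- list()
  for (b in sort(unique(bin))) {
    sel <- bin == b
    out[[labels[b + 1L]]] <- mard(list(ref_bg = ref[sel], est_sbg = est[sel]))
  }
  out
}

#' Full accuracy report for one paired trial
#'
#' Combines MARD, Pearson correlation, error-grid zoning, the fraction of
#' points in zones A+B, lag estimates and rate-stratified MARD into one
#' report for a (reference, estimate) trace pair.
#'
#' @param ref,est [glucose_trace()] objects.
#' @param grid error grid to use, see [error_grid_zone()].
#' @param max_gap pairing tolerance, minutes.
#' @param bin_edges rate bins, mg/dL/min.
#' @param ... further arguments to [lag_estimates()].
#' @return An object of class `accuracy_report`.
#' @export
accuracy_report <- function(ref, est, grid = "consensus_T1D", max_gap = 5,
                            bin_edges = c(-2, -1, 1, 2), ...) {
  pairs <- pair_traces(ref, est, max_gap = max_gap)
  zones <- error_grid_zone(pairs$ref_bg, pairs$est_sbg, grid = grid)
  counts <- table(factor(zones, levels = c("A", "B", "C", "D", "E")))
  lags <- suppressWarnings(lag_estimates(ref, est, ...))
  structure(list(
    mard = mard(pairs),
    pearson_r = if (pairs$N >= 3 && stats::sd(pairs$ref_bg) > 0 &&
                    stats::sd(pairs$est_sbg) > 0)
      stats::cor(pairs$ref_bg, pairs$est_sbg) else NA_real_,
    zone_counts = as.list(counts),
    frac_AB = unname((counts[["A"]] + counts[["B"]]) / pairs$N),
    onset_lag = lags$onset_lag, peak_lag = lags$peak_lag,
    rate_stratified_mard = if (pairs$N >= 2)
      rate_stratified_mard(pairs, bin_edges) else NULL,
    N = pairs$N, grid = grid), class = "accuracy_report")
}

#' @exportS3Method base::print
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> N = %d, MARD = %.2f%%, r = %.3f, A+B = %.1f%%\n",
              x$N, x$mard, x$pearson_r, 100 * x$frac_AB))
  cat("  zones:", paste(names(x$zone_counts), unlist(x$zone_counts),
                        sep = "=", collapse = " "), "\n")
  cat(sprintf("  onset lag = %.1f min, peak lag = %.1f min\n",
              x$onset_lag, x$peak_lag))
  invisible(x)
}
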