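#' Timestamped trace containers
#'
#' Lightweight S3 containers for the signals handled throughout the package.
#' All time axes are in minutes from trial start and must be strictly
#' increasing; glucose is in mg/dL, sensor potential in mV, sweat rate in
#' nL min^-1 cm^-2.
#'
#' @param times numeric vector of timestamps, minutes, strictly increasing.
#' @param values numeric vector, same length as `times`.
#' @param kind for glucose traces, one of `"BG_fingerstick"`, `"CGM"`,
#'   `"SBG"`, `"sweat_proxy"`.
#' @param site for potential traces, `"fingertip"` or `"forearm"`.
#' @return An object of class `glucose_trace`, `potential_trace` or
#'   `sweat_rate_trace`; a list with elements `times`, `values` and the
#'   relevant label.
#' @examples
#' g <- glucose_trace(0:5, rep(90, 6), kind = "BG_fingerstick")
#' g$values
#' @name traces
NULL

trace_kinds <- c("BG_fingerstick", "CGM", "SBG", "sweat_proxy")
trace_sites <- c("fingertip", "forearm")

check_time_axis <- function(times, values, what) {
  if (length(times) != length(values))
    stop(what, ": times and values must have equal length", call. = FALSE)
  if (length(times) < 1L)
    stop(what, ": empty trace", call. = FALSE)
  if (anyNA(times) || anyNA(values))
    stop(what, ": NA in times or values", call. = FALSE)
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop(what, ": times must be strictly increasing (violated at sample ",
         bad, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname traces
#' @export
glucose_trace <- function(times, values, kind = "BG_fingerstick") {
  kind <- match.arg(kind, trace_kinds)
  check_time_axis(times, values, "glucose_trace")
  if (any(values < 0))
    stop("glucose_trace: negative concentration", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind),
            class = c("glucose_trace", "sweatcal_trace"))
}

#' @rdname traces
#' @export
potential_trace <- function(times, values, site = "fingertip") {
  site <- match.arg(site, trace_sites)
  check_time_axis(times, values, "potential_trace")
  if (any(!is.finite(values)))
    stop("potential_trace: non-finite potential", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 site = site),
            class = c("potential_trace", "sweatcal_trace"))
}

#' @rdname traces
#' @export
sweat_rate_trace <- function(times, values) {
  check_time_axis(times, values, "sweat_rate_trace")
  if (any(values < 0))
    stop("sweat_rate_trace: negative sweat rate", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = c("sweat_rate_trace", "sweatcal_trace"))
}

#' @exportS3Method base::print
print.sweatcal_trace <- function(x, ...) {
  lab <- if (!is.null(x$kind)) x$kind else if (!is.null(x$site)) x$site else ""
  cat(sprintf("<%s %s> %d samples, t = [%g, %g] min, range [%g, %g]\n",
              class(x)[1L], lab, length(x$times),
              x$times[1L], x$times[length(x$times)],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Interpolate a trace at new timestamps
#'
#' Linear interpolation of the trace values at the requested times.
#' Times outside the trace span are returned as `NA` unless `rule = 2`
#' (constant extension, the [stats::approx()] convention).
#'
#' @param trace a trace object.
#' @param times numeric vector of query times, minutes.
#' @param rule extrapolation rule passed to [stats::approx()].
#' @return numeric vector of interpolated values.
#' @export
trace_at <- function(trace, times, rule = 1) {
  if (length(trace$times) == 1L) {
    out <- rep(trace$values, length(times))
    if (rule == 1) out[times != trace$times] <- NA_real_
    return(out)
  }
  stats::approx(trace$times, trace$values, xout = times, rule = rule)$y
}
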