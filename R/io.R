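#' Read and write trace files
#'
#' Traces are stored as plain delimited text with a one-line header
#' `time_min,value` — easy to inspect and diff. Writing then reading a
#' trace reproduces its values at full double precision (values are
#' serialized with 17 significant digits). Malformed files are rejected
#' with the offending line number.
#'
#' @param trace a trace object ([glucose_trace()], [potential_trace()] or
#'   [sweat_rate_trace()]).
#' @param path file path.
#' @param kind,site metadata used to rebuild the right trace class on
#'   read; `kind = NULL` (with `site`) yields a potential trace,
#'   `kind = "sweat_rate"` a sweat-rate trace, otherwise a glucose trace
#'   of that kind.
#' @return `write_trace()` returns `path` invisibly; `read_trace()`
#'   returns the trace object.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_trace(glucose_trace(0:3, c(90, 91, 92, 93)), f)
#' read_trace(f)
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sweatcal_trace"))
  df <- data.frame(time_min = sprintf("%.17g", trace$times),
                   value = sprintf("%.17g", trace$values))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, kind = "BG_fingerstick", site = "fingertip") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L || all(!nzchar(lines)))
    stop("empty trace file: ", path, call. = FALSE)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(header[1:2]), c("time_min", "value")))
    stop("bad header in ", path, ": expected 'time_min,value'",
         call. = FALSE)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) stop("trace file has a header but no data: ", path,
                          call. = FALSE)
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad))
    stop("malformed row at line ", bad[1L] + 1L, " of ", path,
         call. = FALSE)
  times <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  values <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(times) || anyNA(values)) {
    bad <- which(is.na(times) | is.na(values))[1L]
    stop("non-numeric value at line ", bad + 1L, " of ", path,
         call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop("non-monotone time column at line ", bad + 1L, " of ", path,
         call. = FALSE)
  }
  if (is.null(kind)) return(potential_trace(times, values, site = site))
  if (identical(kind, "sweat_rate")) return(sweat_rate_trace(times, values))
  glucose_trace(times, values, kind = kind)
}

#' Serialize calibration parameters to and from JSON
#'
#' @param params a [calibration_params()] object.
#' @param path JSON file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` the reconstructed [calibration_params()].
#' @export
write_calibration <- function(params, path) {
  stopifnot(inherits(params, "calibration_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_params(E_o = x$E_o, dE_max = x$dE_max, BG_f = x$BG_f,
                     BG_max = x$BG_max, subject_id = x$subject_id,
                     site = x$site,
                     fitted_on = if (is.null(x$fitted_on)) NA else x$fitted_on)
}

#' Write a full synthetic trial to a directory
#'
#' One CSV per trace (`bg.csv`, `sweat.csv`, `potential.csv`, `cgm.csv`,
#' `sweat_rate.csv`) plus a `profile.json` sidecar recording the
#' generating [subject_profile()] and a provenance hash.
#'
#' @param trial a trial bundle from [simulate_trial()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trace(trial$bg, file.path(dir, "bg.csv"))
  write_trace(trial$sweat, file.path(dir, "sweat.csv"))
  write_trace(trial$potential, file.path(dir, "potential.csv"))
  write_trace(trial$cgm, file.path(dir, "cgm.csv"))
  write_trace(trial$sweat_rate, file.path(dir, "sweat_rate.csv"))
  sidecar <- c(unclass(trial$profile),
               list(provenance = trial$provenance))
  jsonlite::write_json(sidecar, file.path(dir, "profile.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# stable short hash of a configuration list (polynomial rolling hash over
# its deparse; all intermediates stay exactly representable in doubles)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
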