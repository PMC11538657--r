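#' Parkes (consensus) error-grid boundaries for type-1 diabetes
#'
#' Published vertex coordinates of the zone boundaries of the Parkes
#' consensus error grid for type-1 diabetes, as digitized by Pfuetzner et
#' al. (2013), in mg/dL on the (reference, estimate) plane. Each boundary
#' is a polyline; `upper` boundaries separate zones above the identity
#' line, `lower` boundaries below it. The same vertices are shipped as a
#' plain-text asset in `inst/extdata/parkes_t1d_vertices.csv`.
#'
#' @return A named list of two-column matrices (`ref`, `est`):
#'   `AB_upper`, `BC_upper`, `CD_upper`, `DE_upper`, `AB_lower`,
#'   `BC_lower`, `CD_lower`.
#' @export
parkes_t1d_vertices <- function() {
  m <- function(...) {
    v <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(v) <- c("ref", "est")
    v
  }
  list(
    AB_upper = m(0, 50, 30, 50, 140, 170, 280, 380, 430, 550),
    BC_upper = m(0, 60, 30, 60, 50, 80, 70, 110, 260, 550),
    CD_upper = m(0, 100, 25, 100, 50, 125, 80, 215, 125, 550),
    DE_upper = m(0, 150, 35, 155, 50, 550),
    AB_lower = m(50, 0, 50, 30, 170, 145, 385, 300, 550, 450),
    BC_lower = m(120, 0, 120, 30, 260, 130, 550, 250),
    CD_lower = m(250, 0, 250, 40, 550, 150)
  )
}

#' Parkes T1D zone polygons
#'
#' Closed polygons (columns `ref`, `est`) for zones A-E over the 0-550
#' mg/dL plot range, assembled from [parkes_t1d_vertices()]. Useful for
#' plotting and for independent point-in-polygon checks.
#'
#' @return Named list of two-column matrices, one per zone.
#' @export
parkes_zone_polygons <- function() {
  m <- function(...) {
    v <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(v) <- c("ref", "est")
    v
  }
  list(
    A = m(0, 0, 50, 0, 50, 30, 170, 145, 385, 300, 550, 450, 550, 550,
          430, 550, 280, 380, 140, 170, 30, 50, 0, 50),
    B = list(
      upper = m(0, 50, 30, 50, 140, 170, 280, 380, 430, 550, 260, 550,
                70, 110, 50, 80, 30, 60, 0, 60),
      lower = m(50, 0, 120, 0, 120, 30, 260, 130, 550, 250, 550, 450,
                385, 300, 170, 145, 50, 30)),
    C = list(
      upper = m(0, 60, 30, 60, 50, 80, 70, 110, 260, 550, 125, 550,
                80, 215, 50, 125, 25, 100, 0, 100),
      lower = m(120, 0, 250, 0, 250, 40, 550, 150, 550, 250, 260, 130,
                120, 30)),
    D = list(
      upper = m(0, 100, 25, 100, 50, 125, 80, 215, 125, 550, 50, 550,
                35, 155, 0, 150),
      lower = m(250, 0, 550, 0, 550, 150, 250, 40)),
    E = m(0, 150, 35, 155, 50, 550, 0, 550)
  )
}

# piecewise-linear boundary value at `x`, extended beyond the published
# vertices with the end-segment slopes
pw_boundary <- function(verts) {
  xs <- verts[, 1L]; ys <- verts[, 2L]
  n <- length(xs)
  function(x) {
    y <- stats::approx(xs, ys, xout = x, rule = 1, ties = "ordered")$y
    lo <- x < xs[1L]
    if (any(lo))
      y[lo] <- ys[1L] + (x[lo] - xs[1L]) * (ys[2L] - ys[1L]) / (xs[2L] - xs[1L])
    hi <- x > xs[n]
    if (any(hi))
      y[hi] <- ys[n] + (x[hi] - xs[n]) *
        (ys[n] - ys[n - 1L]) / (xs[n] - xs[n - 1L])
    y
  }
}
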