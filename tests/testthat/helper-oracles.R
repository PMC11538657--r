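# Independent geometric oracle: even-odd ray casting, written without any
# of the package's boundary-function machinery.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1L]; ys <- poly[, 2L]
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py)) {
      x_cross <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      if (px < x_cross) inside <- !inside
    }
    j <- i
  }
  inside
}

# zone of one point by testing the published polygons from lowest risk up
parkes_zone_oracle <- function(ref, est) {
  polys <- parkes_zone_polygons()
  test_zone <- function(z) {
    p <- polys[[z]]
    if (is.list(p) && !is.matrix(p))
      any(vapply(p, function(q) point_in_polygon(ref, est, q), logical(1)))
    else point_in_polygon(ref, est, p)
  }
  for (z in c("A", "B", "C", "D", "E")) if (test_zone(z)) return(z)
  NA_character_
}

# profile used wherever an exactly invertible trial is needed
noiseless_profile <- function(...) {
  subject_profile(noise_sd = 0, drift_rate = 0, smoothing_tau = 0,
                  ...)
}

# full noiseless trial with dense reference sampling
noiseless_trial <- function(profile, duration = 240) {
  bg <- gen_bg_profile(profile, duration, step = 1)
  sweat <- blood_to_sweat(bg, profile$onset_lag, profile$smoothing_tau)
  E <- gen_potential(sweat, profile)
  list(bg = bg, sweat = sweat, E = E)
}
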