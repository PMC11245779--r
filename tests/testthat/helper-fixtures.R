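# Fixture builders shared across the suite.  Everything is generated in code.

# a normalized_cycle from raw hip/knee vectors on the standard grid
make_cycle <- function(hip, knee, centered = FALSE, n_points = length(hip)) {
  structure(list(grid = seq(0, 100, length.out = n_points),
                 hip = hip, knee = knee, centered = centered),
            class = "normalized_cycle")
}

# centered sine-wave cycle: hip = a*sin(2*pi*t + ph), knee = b*sin(2*pi*t + ph)
sine_cycle <- function(a = 10, b = 20, ph = 0, n_points = 101L) {
  t <- seq(0, 1, length.out = n_points)
  make_cycle(a * sin(2 * pi * t + ph), b * sin(2 * pi * t + ph),
             centered = TRUE)
}

# template converted to a (centered) normalized cycle
template_cycle <- function(speed = "preferred", center = TRUE) {
  tpl <- gait_template(speed)
  cy <- make_cycle(tpl$hip, tpl$knee)
  if (center) mean_center(cy) else cy
}

# zero-noise effect configuration
quiet_effect <- function(...) {
  effect_config(amp_noise_sd = 0, phase_noise_sd = 0, meas_noise_sd = 0,
                duration_jitter = 0, ...)
}

# naive independent ACC oracle: per-frame circular resultant of segment
# angles computed via complex arithmetic
acc_oracle <- function(cycles) {
  angs <- vapply(cycles, function(cy) {
    atan2(diff(cy$knee), diff(cy$hip))
  }, numeric(length(cycles[[1]]$hip) - 1L))
  mean(abs(rowMeans(exp(1i * angs))))
}
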