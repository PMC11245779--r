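# Normative sagittal hip/knee gait templates.
#
# The curves are smooth periodic waveforms built from keypoints of standard
# adult sagittal-plane gait kinematics (flexion positive): hip flexed ~30 deg
# at initial contact, peak extension in late stance, peak flexion in late
# swing; knee with a loading-response bump, near-extension in mid stance and
# a large swing-phase flexion peak.  Keypoints are interpolated with a
# periodic spline and projected onto a truncated Fourier basis, which
# guarantees exact periodicity and smooth derivatives.

# keypoints: percent gait cycle, degrees (preferred-speed shape)
.hip_keypoints <- cbind(
  pct = c(0, 10, 20, 30, 40, 50, 55, 60, 70, 80, 85, 90, 100),
  deg = c(30, 25, 15, 4, -6, -10, -9, -4, 13, 28, 31, 31, 30)
)

.knee_keypoints <- cbind(
  pct = c(0, 10, 15, 20, 30, 40, 45, 50, 55, 60, 64, 69, 72, 75, 79, 85, 90, 95, 100),
  deg = c(5, 16, 18, 14, 6, 3, 3.5, 6, 14, 32, 52, 62, 65, 63, 55, 36, 17, 8, 5)
)

# Per-speed amplitude scales relative to the preferred-speed shape, chosen so
# template ranges of motion follow the typical healthy speed gradient
# (hip ROM ~46/41/33 deg and knee ROM ~64/62/59 deg at fast/preferred/slow).
.speed_params <- list(
  fast      = list(hip_scale = 46 / 41, knee_scale = 64 / 62, toe_off = 58, duration = 0.95),
  preferred = list(hip_scale = 1,       knee_scale = 1,       toe_off = 60, duration = 1.10),
  slow      = list(hip_scale = 33 / 41, knee_scale = 59 / 62, toe_off = 62, duration = 1.40)
)

# Truncated Fourier reconstruction of a periodic curve given on a fine grid.
fourier_smooth <- function(pct, deg, n_harmonics = 8L, grid = seq(0, 100, by = 1)) {
  stopifnot(n_harmonics >= 1L)
  # dense periodic resample (exclude duplicated endpoint for the transform)
  fine <- seq(0, 100, length.out = 401L)
  y <- spline(pct, deg, xout = fine, method = "periodic")$y
  t <- fine[-length(fine)] / 100
  y <- y[-length(y)]
  n <- length(y)
  a0 <- mean(y)
  out <- rep(a0, length(grid))
  tg <- grid / 100
  for (k in seq_len(n_harmonics)) {
    ak <- 2 * mean(y * cos(2 * pi * k * t))
    bk <- 2 * mean(y * sin(2 * pi * k * t))
    out <- out + ak * cos(2 * pi * k * tg) + bk * sin(2 * pi * k * tg)
  }
  out
}

#' Normative hip-knee gait cycle template
#'
#' Builds the package's normative sagittal hip and knee angle curves for one
#' walking speed, sampled on a fixed percent-gait-cycle grid.  Curves are
#' Fourier-series (default 8 harmonics) reconstructions of keypoint shapes of
#' healthy adult gait; the speed determines amplitude scaling, toe-off timing
#' and nominal cycle duration.  These templates are the backbone of the
#' synthetic cohort generator.
#'
#' @param speed walking-speed label: `"slow"`, `"preferred"` or `"fast"`.
#' @param n_points number of grid points spanning 0--100% gait cycle
#'   (inclusive); default 101.
#' @param n_harmonics number of Fourier harmonics used to smooth the keypoint
#'   shape (minimum 6 recommended; default 8).
#' @return An object of class `gait_template`: a list with `grid` (percent
#'   gait cycle), `hip` and `knee` (degrees, flexion positive), `toe_off_pct`,
#'   `cycle_duration_s` and `speed`.
#' @examples
#' tpl <- gait_template("preferred")
#' range(tpl$knee)
#' plot(tpl)
#' @export
gait_template <- function(speed = c("preferred", "slow", "fast"),
                          n_points = 101L, n_harmonics = 8L) {
  speed <- match.arg(speed)
  stopifnot(n_points >= 3L, n_harmonics >= 1L)
  p <- .speed_params[[speed]]
  grid <- seq(0, 100, length.out = n_points)
  hip <- fourier_smooth(.hip_keypoints[, "pct"], .hip_keypoints[, "deg"],
                        n_harmonics, grid)
  knee <- fourier_smooth(.knee_keypoints[, "pct"], .knee_keypoints[, "deg"],
                         n_harmonics, grid)
  hip <- mean(hip) + p$hip_scale * (hip - mean(hip))
  knee <- mean(knee) + p$knee_scale * (knee - mean(knee))
  structure(
    list(grid = grid, hip = hip, knee = knee,
         toe_off_pct = p$toe_off, cycle_duration_s = p$duration,
         speed = speed),
    class = "gait_template"
  )
}

#' @export
print.gait_template <- function(x, ...) {
  cat(sprintf("Gait template (%s speed)\n", x$speed))
  cat(sprintf("  grid: %d points over 0-100%% gait cycle\n", length(x$grid)))
  cat(sprintf("  hip ROM: %.1f deg, knee ROM: %.1f deg\n",
              diff(range(x$hip)), diff(range(x$knee))))
  cat(sprintf("  toe-off: %.0f%%, cycle duration: %.2f s\n",
              x$toe_off_pct, x$cycle_duration_s))
  invisible(x)
}

#' @export
plot.gait_template <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(x$grid, x$hip, type = "l", xlab = "% gait cycle",
       ylab = "hip flexion [deg]", main = paste("hip,", x$speed), ...)
  abline(v = x$toe_off_pct, lty = 2)
  plot(x$grid, x$knee, type = "l", xlab = "% gait cycle",
       ylab = "knee flexion [deg]", main = paste("knee,", x$speed), ...)
  abline(v = x$toe_off_pct, lty = 2)
  invisible(x)
}
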