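# Cyclogram (hip-knee angle-angle) coordination variables: joint ranges of
# motion, the angular coefficient of correspondence (ACC), the sum of
# squared distances between cyclogram shapes (SSD), extremal cyclogram
# points, and between-speed adaptation ratios.

#' Cyclogram of one (or an average) gait cycle
#'
#' Pairs the mean-centered hip and knee curves of a normalized cycle into an
#' ordered set of angle-angle points whose centroid is at the origin.
#'
#' @param cycle a mean-centered `normalized_cycle` (see [mean_center()]), or
#'   a list of them, in which case the point-wise average cyclogram is
#'   returned.
#' @return Object of class `cyclogram`: list with `grid`, `hip`, `knee`.
#' @export
cyclogram <- function(cycle) {
  if (inherits(cycle, "normalized_cycle")) cycle <- list(cycle)
  stopifnot(length(cycle) >= 1, all(vapply(cycle, inherits, logical(1),
                                           "normalized_cycle")))
  if (!all(vapply(cycle, `[[`, logical(1), "centered")))
    stop("cyclograms require mean-centered cycles")
  grid <- cycle[[1]]$grid
  hip <- rowMeans(vapply(cycle, `[[`, numeric(length(grid)), "hip"))
  knee <- rowMeans(vapply(cycle, `[[`, numeric(length(grid)), "knee"))
  structure(list(grid = grid, hip = hip - mean(hip), knee = knee - mean(knee)),
            class = "cyclogram")
}

#' @export
plot.cyclogram <- function(x, ...) {
  plot(x$hip, x$knee, type = "l", xlab = "hip flexion [deg, centered]",
       ylab = "knee flexion [deg, centered]", asp = 1, ...)
  points(0, 0, pch = 3, col = "red", lwd = 2)
  ex <- extremal_points(x)
  i_min <- which.min(abs(x$grid - ex$min$location_pct))
  i_max <- which.min(abs(x$grid - ex$max$location_pct))
  points(x$hip[i_min], x$knee[i_min], pch = 1, cex = 1.5)
  points(x$hip[i_max], x$knee[i_max], pch = 8, cex = 1.5)
  invisible(x)
}

#' Range of motion of an angle curve
#'
#' `max - min` of the curve in degrees.  For a list of cycles, the mean of
#' the per-cycle ranges (the trial-level ROM).
#'
#' @param x numeric angle series, a `normalized_cycle`, or a list of cycles.
#' @param joint which joint when `x` holds cycles: `"hip"` or `"knee"`.
#' @return ROM in degrees.
#' @export
rom <- function(x, joint = c("hip", "knee")) {
  if (is.numeric(x)) {
    if (length(x) < 2) stop("need at least 2 samples")
    return(diff(range(x)))
  }
  joint <- match.arg(joint)
  if (inherits(x, "normalized_cycle")) x <- list(x)
  mean(vapply(x, function(cy) diff(range(cy[[joint]])), numeric(1)))
}

# Direction cosines of cyclogram segments of one cycle: (N-1) x 2 matrix of
# (cos, sin) of the segment between consecutive grid points.  Zero-length
# segments carry the previous segment's direction (the first zero-length
# segments take the first defined direction).
segment_directions <- function(cycle) {
  dh <- diff(cycle$hip)
  dk <- diff(cycle$knee)
  len <- sqrt(dh^2 + dk^2)
  if (all(len == 0)) stop("degenerate cycle: all segments have zero length")
  cosd <- dh / len
  sind <- dk / len
  bad <- which(len == 0)
  if (length(bad)) {
    good <- which(len > 0)
    for (i in bad) {
      j <- if (any(good < i)) max(good[good < i]) else min(good)
      cosd[i] <- cosd[j]
      sind[i] <- sind[j]
    }
  }
  cbind(cos = cosd, sin = sind)
}

#' Angular coefficient of correspondence (ACC)
#'
#' Quantifies cycle-to-cycle consistency of the hip-knee angular
#' relationship.  For each frame (pair of consecutive grid points), the
#' direction of the cyclogram segment is expressed as a unit vector; across
#' the cycles of a trial the circular mean resultant length of these
#' directions is computed per frame, and ACC is the mean resultant length
#' over frames.  1 indicates perfectly repeatable segment directions, 0 no
#' consistency.
#'
#' @param cycles list of >= 2 mean-centered `normalized_cycle`s on a common
#'   grid.
#' @param variant `"resultant"` (default): resultant across all cycles per
#'   frame; `"consecutive"`: mean of the two-cycle resultants of consecutive
#'   cycle pairs.
#' @return ACC in `[0, 1]`.
#' @examples
#' tpl <- gait_template("preferred")
#' cyc <- mean_center(structure(list(grid = tpl$grid, hip = tpl$hip,
#'   knee = tpl$knee, centered = FALSE), class = "normalized_cycle"))
#' acc(list(cyc, cyc, cyc))  # identical cycles: exactly 1
#' @export
acc <- function(cycles, variant = c("resultant", "consecutive")) {
  variant <- match.arg(variant)
  stopifnot(is.list(cycles))
  if (length(cycles) < 2) stop("ACC needs at least 2 cycles")
  grids <- vapply(cycles, function(cy) length(cy$grid), integer(1))
  if (length(unique(grids)) != 1) stop("cycles must share one grid")
  dirs <- lapply(cycles, segment_directions)
  resultant <- function(idx) {
    cbar <- rowMeans(vapply(dirs[idx], function(d) d[, "cos"],
                            numeric(nrow(dirs[[1]]))))
    sbar <- rowMeans(vapply(dirs[idx], function(d) d[, "sin"],
                            numeric(nrow(dirs[[1]]))))
    a <- sqrt(cbar^2 + sbar^2)
    # coincident directions must yield exactly 1; snap away rounding fuzz
    a[a > 1 - 1e-12] <- 1
    mean(a)
  }
  if (variant == "resultant") {
    resultant(seq_along(dirs))
  } else {
    mean(vapply(seq_len(length(dirs) - 1L),
                function(j) resultant(c(j, j + 1L)), numeric(1)))
  }
}

#' Sum of squared distances (SSD) between two cyclograms
#'
#' Point-wise shape discrepancy between two cyclograms on the same grid.
#' The default convention is the root-mean-square Euclidean distance between
#' corresponding points (degrees), which is commensurate with the joint
#' angles themselves; the raw sum of squared distances is available via
#' `convention = "sum"`.
#'
#' @param a,b `cyclogram`s (or mean-centered `normalized_cycle`s) on the
#'   same grid.
#' @param convention `"rms"` (default) or `"sum"`.
#' @return SSD (degrees for `"rms"`; squared degrees summed for `"sum"`).
#' @export
ssd <- function(a, b, convention = c("rms", "sum")) {
  convention <- match.arg(convention)
  if (inherits(a, "normalized_cycle")) a <- cyclogram(a)
  if (inherits(b, "normalized_cycle")) b <- cyclogram(b)
  if (length(a$grid) != length(b$grid)) stop("cyclograms must share one grid")
  d2 <- (a$hip - b$hip)^2 + (a$knee - b$knee)^2
  if (convention == "rms") sqrt(mean(d2)) else sum(d2)
}

#' Trial-level SSD across consecutive cycles
#'
#' Mean SSD over consecutive cycle pairs within a trial (the within-trial
#' cycle-to-cycle variability).
#'
#' @param cycles list of >= 2 mean-centered cycles on a common grid.
#' @param convention passed to [ssd()].
#' @return Trial-level SSD.
#' @export
trial_ssd <- function(cycles, convention = c("rms", "sum")) {
  convention <- match.arg(convention)
  if (length(cycles) < 2) stop("trial SSD needs at least 2 cycles")
  mean(vapply(seq_len(length(cycles) - 1L), function(j)
    ssd(cycles[[j]], cycles[[j + 1L]], convention), numeric(1)))
}

#' Extremal cyclogram points
#'
#' Minimum and maximum of the combined centered flexion `hip + knee` over
#' the grid.  The minimum corresponds to late stance (weight transfer to the
#' forefoot just before toe-off), the maximum to peak combined flexion in
#' mid-swing.  Magnitude is the Euclidean distance of the extremal point
#' from the cyclogram centroid.  Ties are broken by the earliest percent of
#' the gait cycle.
#'
#' @param cg a `cyclogram` (or mean-centered `normalized_cycle`).
#' @return List with `min` and `max`, each a list
#'   `(location_pct, magnitude_deg, kind)`.
#' @export
extremal_points <- function(cg) {
  if (inherits(cg, "normalized_cycle")) cg <- cyclogram(cg)
  s <- cg$hip + cg$knee
  if (diff(range(s)) < 1e-9)
    stop("degenerate cyclogram: combined flexion is constant")
  i_min <- which.min(s)  # which.min/max return the earliest tie
  i_max <- which.max(s)
  pt <- function(i, kind) list(location_pct = cg$grid[i],
                               magnitude_deg = sqrt(cg$hip[i]^2 + cg$knee[i]^2),
                               kind = kind)
  list(min = pt(i_min, "min"), max = pt(i_max, "max"))
}

#' Per-trial cyclogram metrics
#'
#' Computes all scalar coordination variables of a trial from its normalized
#' mean-centered cycles: hip and knee ROM (mean of per-cycle ranges), ACC,
#' within-trial SSD, and the locations/magnitudes of the extremal cyclogram
#' points (mean over cycles).
#'
#' @param cycles list of >= 2 mean-centered `normalized_cycle`s.
#' @param acc_variant,ssd_convention see [acc()] and [ssd()].
#' @return One-row data frame: `rom_hip`, `rom_knee`, `acc`, `ssd`,
#'   `min_pct`, `min_mag`, `max_pct`, `max_mag`.
#' @export
trial_metrics <- function(cycles, acc_variant = c("resultant", "consecutive"),
                          ssd_convention = c("rms", "sum")) {
  stopifnot(length(cycles) >= 2)
  ex <- lapply(cycles, extremal_points)
  circ_mean_pct <- function(p) {
    # locations are circular in the gait cycle; average on the circle
    th <- p * 2 * pi / 100
    (atan2(mean(sin(th)), mean(cos(th))) %% (2 * pi)) * 100 / (2 * pi)
  }
  data.frame(
    rom_hip = rom(cycles, "hip"),
    rom_knee = rom(cycles, "knee"),
    acc = acc(cycles, match.arg(acc_variant)),
    ssd = trial_ssd(cycles, match.arg(ssd_convention)),
    min_pct = circ_mean_pct(vapply(ex, function(e) e$min$location_pct, numeric(1))),
    min_mag = mean(vapply(ex, function(e) e$min$magnitude_deg, numeric(1))),
    max_pct = circ_mean_pct(vapply(ex, function(e) e$max$location_pct, numeric(1))),
    max_mag = mean(vapply(ex, function(e) e$max$magnitude_deg, numeric(1)))
  )
}

#' Between-speed adaptation ratios of extremal-point magnitudes
#'
#' For a faster condition A and slower condition B: the ratio of minimum-
#' point magnitudes, the ratio of maximum-point magnitudes, and their
#' quotient (the "ratio of minimum points to ratio of maximum points").
#' Low values of the quotient indicate late, high values early adaptation of
#' joint excursions to increased walking speed.
#'
#' @param metrics_fast,metrics_slow one-row data frames from
#'   [trial_metrics()] for the faster and slower condition of the pair.
#' @param comparison optional label, e.g. `"fast_vs_slow"`.
#' @return One-row data frame: `ratio_min`, `ratio_max`, `ratio_of_ratios`,
#'   `comparison`.
#' @export
speed_adaptation_ratio <- function(metrics_fast, metrics_slow,
                                   comparison = "A_vs_B") {
  if (metrics_slow$min_mag <= 0 || metrics_slow$max_mag <= 0)
    stop("zero extremal-point magnitude in the slower condition")
  ratio_min <- metrics_fast$min_mag / metrics_slow$min_mag
  ratio_max <- metrics_fast$max_mag / metrics_slow$max_mag
  data.frame(ratio_min = ratio_min, ratio_max = ratio_max,
             ratio_of_ratios = ratio_min / ratio_max,
             comparison = comparison, stringsAsFactors = FALSE)
}

#' Express a speed-adaptation ratio as a percent difference
#'
#' Maps a ratio r to `(r - 1) * 100`, the percent difference between the
#' two conditions (e.g. a fast-vs-slow ratio of 1.61 is a 61% difference).
#'
#' @param ratio a positive ratio.
#' @return Percent difference.
#' @export
ratio_percent_difference <- function(ratio) {
  stopifnot(is.numeric(ratio), all(ratio > 0))
  (ratio - 1) * 100
}
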