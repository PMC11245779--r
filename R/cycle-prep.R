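# Preprocessing of raw angle time series: cycle segmentation at
# initial-contact events, linear time normalization onto a fixed
# percent-gait-cycle grid, mean-centering, and a configurable QC hook.

#' Construct an angle time series object
#'
#' Container for one trial of sampled sagittal hip/knee angles with
#' initial-contact event annotations (the pipeline's raw input).
#'
#' @param hip,knee equal-length numeric vectors of joint angles in degrees
#'   (flexion positive).
#' @param events strictly increasing 0-based sample indices of initial
#'   contacts, all within the series bounds.
#' @param rate sampling rate in Hz.
#' @param subject_id,group,speed metadata labels.
#' @return Object of class `angle_ts`.
#' @export
angle_ts <- function(hip, knee, events, rate = 200,
                     subject_id = "S01", group = "control",
                     speed = "preferred") {
  if (length(hip) != length(knee)) stop("hip and knee must have equal length")
  events <- as.integer(events)
  if (any(diff(events) <= 0)) stop("events must be strictly increasing")
  if (length(events) && (min(events) < 0 || max(events) >= length(hip)))
    stop("events out of series bounds")
  if (rate <= 0) stop("sampling rate must be positive")
  structure(list(subject_id = subject_id, group = group, speed = speed,
                 rate = rate, hip = as.numeric(hip), knee = as.numeric(knee),
                 events = events),
            class = "angle_ts")
}

#' Segment a trial into raw gait cycles
#'
#' One cycle per consecutive pair of initial-contact events, as the half-open
#' sample slice `[IC_k, IC_{k+1})`.
#'
#' @param ts an [angle_ts()].
#' @return List of raw cycles, each a list with numeric `hip` and `knee`.
#' @export
segment_cycles <- function(ts) {
  stopifnot(inherits(ts, "angle_ts"))
  ev <- ts$events
  if (length(ev) < 2) stop("need at least 2 initial-contact events")
  if (any(diff(ev) <= 0)) stop("events must be strictly increasing")
  lapply(seq_len(length(ev) - 1L), function(k) {
    i <- (ev[k] + 1L):ev[k + 1L]  # 0-based [IC_k, IC_{k+1}) -> 1-based indices
    list(hip = ts$hip[i], knee = ts$knee[i])
  })
}

#' Time-normalize a raw cycle onto the percent-gait-cycle grid
#'
#' Linear interpolation of both joints onto `n_points` equally spaced points
#' spanning 0--100% of the cycle; the first and last raw samples map exactly
#' to 0% and 100%.
#'
#' @param cycle a raw cycle (list with `hip`, `knee`) from [segment_cycles()].
#' @param n_points grid size, default 101 (0, 1, ..., 100%).
#' @return Object of class `normalized_cycle`: list with `grid`, `hip`,
#'   `knee`, `centered` (logical).
#' @export
time_normalize <- function(cycle, n_points = 101L) {
  n <- length(cycle$hip)
  if (n < 3) stop("cycle too short to normalize (need >= 3 samples)")
  if (n_points < 3) stop("n_points must be >= 3")
  grid <- seq(0, 100, length.out = n_points)
  x <- seq(0, 100, length.out = n)
  structure(list(grid = grid,
                 hip = approx(x, cycle$hip, xout = grid)$y,
                 knee = approx(x, cycle$knee, xout = grid)$y,
                 centered = FALSE),
            class = "normalized_cycle")
}

#' Mean-center a normalized cycle
#'
#' Subtracts each joint's own cycle mean so the cyclogram centroid is at the
#' origin.  Idempotent; translation of either joint's raw angles leaves the
#' output unchanged.
#'
#' @param cycle a `normalized_cycle`.
#' @return The centered `normalized_cycle`.
#' @export
mean_center <- function(cycle) {
  stopifnot(inherits(cycle, "normalized_cycle"))
  cycle$hip <- cycle$hip - mean(cycle$hip)
  cycle$knee <- cycle$knee - mean(cycle$knee)
  cycle$centered <- TRUE
  cycle
}

#' Quality-control rules for trials
#'
#' The study-specific exclusion criteria for joint-angle trials are a
#' pluggable hook; the defaults reject physiologically impossible angles and
#' near-constant (no-movement) trials.
#'
#' @param max_abs_deg reject if any |angle| exceeds this (default 120).
#' @param min_rom_deg reject if any cycle's ROM (either joint) is below this
#'   (default 5).
#' @return List of rules for [qc_trial()].
#' @export
qc_rules <- function(max_abs_deg = 120, min_rom_deg = 5) {
  list(max_abs_deg = max_abs_deg, min_rom_deg = min_rom_deg)
}

#' Apply quality control to a trial
#'
#' @param ts an [angle_ts()].
#' @param rules a [qc_rules()] list.
#' @return List with `keep` (logical) and `reasons` (character vector of the
#'   rules that fired, empty if kept).
#' @export
qc_trial <- function(ts, rules = qc_rules()) {
  stopifnot(inherits(ts, "angle_ts"))
  reasons <- character(0)
  if (max(abs(c(ts$hip, ts$knee))) > rules$max_abs_deg)
    reasons <- c(reasons, "range")
  if (length(ts$events) >= 2) {
    cycles <- segment_cycles(ts)
    roms <- vapply(cycles, function(cy)
      min(diff(range(cy$hip)), diff(range(cy$knee))), numeric(1))
    if (any(roms < rules$min_rom_deg)) reasons <- c(reasons, "rom")
  }
  list(keep = length(reasons) == 0, reasons = reasons)
}

#' Segment, normalize and center all cycles of a trial
#'
#' Convenience wrapper: [segment_cycles()], then [time_normalize()] and
#' (optionally) [mean_center()] per cycle.
#'
#' @param ts an [angle_ts()].
#' @param n_points grid size (default 101).
#' @param center mean-center each cycle (default `TRUE`).
#' @return List of `normalized_cycle` objects.
#' @export
prep_trial <- function(ts, n_points = 101L, center = TRUE) {
  cycles <- lapply(segment_cycles(ts), time_normalize, n_points = n_points)
  if (center) cycles <- lapply(cycles, mean_center)
  cycles
}
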