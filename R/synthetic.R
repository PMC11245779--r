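# Synthetic gait-kinematics generator: event-annotated hip/knee sagittal
# angle time series for cohorts with controlled group effects (ROM scaling,
# delayed hip-flexion peak, swing-confined knee deficit) and cycle-to-cycle
# variability (amplitude, phase and duration jitter, measurement noise).

#' Effect configuration for the synthetic gait generator
#'
#' Bundles the deterministic group effects and stochastic variability applied
#' to a normative template when simulating one trial.
#'
#' @param hip_rom_scale,knee_rom_scale unitless multipliers (> 0) applied to
#'   each joint's curve about its mean; scale the joint's range of motion
#'   exactly.
#' @param hip_peak_delay_pct delay (percent gait cycle, `0 <= d < 25`) of the
#'   swing-phase hip-flexion peak, implemented as a monotone piecewise-linear
#'   time warp confined to the swing portion of the cycle.
#' @param knee_swing_deficit_deg peak depth (degrees, >= 0) of a smooth
#'   raised-cosine reduction of knee flexion over the 60--90% swing window,
#'   emulating a swing-confined knee deficit.
#' @param amp_noise_sd per-cycle fractional amplitude jitter (SD of a
#'   multiplicative factor `1 + e`, per joint per cycle).
#' @param phase_noise_sd per-cycle timing jitter, SD in percent gait cycle.
#' @param meas_noise_sd additive measurement noise SD in degrees, per sample.
#' @param cycle_duration_s nominal cycle duration in seconds; if `NA` the
#'   template's speed-specific duration is used.
#' @param duration_jitter SD of the log cycle duration (log-normal jitter).
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(hip_rom_scale = 1, knee_rom_scale = 1,
                          hip_peak_delay_pct = 0, knee_swing_deficit_deg = 0,
                          amp_noise_sd = 0.06, phase_noise_sd = 1.5,
                          meas_noise_sd = 0.1, cycle_duration_s = NA_real_,
                          duration_jitter = 0.03) {
  stopifnot(hip_rom_scale > 0, knee_rom_scale > 0,
            hip_peak_delay_pct >= 0, hip_peak_delay_pct < 25,
            knee_swing_deficit_deg >= 0,
            amp_noise_sd >= 0, phase_noise_sd >= 0, meas_noise_sd >= 0,
            is.na(cycle_duration_s) || cycle_duration_s > 0,
            duration_jitter >= 0)
  structure(list(hip_rom_scale = hip_rom_scale, knee_rom_scale = knee_rom_scale,
                 hip_peak_delay_pct = hip_peak_delay_pct,
                 knee_swing_deficit_deg = knee_swing_deficit_deg,
                 amp_noise_sd = amp_noise_sd, phase_noise_sd = phase_noise_sd,
                 meas_noise_sd = meas_noise_sd,
                 cycle_duration_s = cycle_duration_s,
                 duration_jitter = duration_jitter),
            class = "effect_config")
}

# raised-cosine bump with support [60, 90], peak 1 at 75% gait cycle
swing_bump <- function(pct) {
  out <- numeric(length(pct))
  i <- abs(pct - 75) < 15
  out[i] <- 0.5 * (1 + cos(pi * (pct[i] - 75) / 15))
  out
}

# monotone piecewise-linear warp of the phase axis delaying the swing hip
# peak at p0 by d, fixed at 0, toe-off and 100; returns the inverse map
# evaluated at `pct` (i.e., which template phase is seen at output phase pct)
delay_warp_inverse <- function(pct, toe_off, p0, d) {
  if (d <= 0) return(pct)
  if (p0 + d >= 99) stop("hip peak delay too large for this template")
  approx(x = c(0, toe_off, p0 + d, 100), y = c(0, toe_off, p0, 100),
         xout = pct, rule = 2)$y
}

#' Simulate one walking trial from a gait template
#'
#' Concatenates `n_cycles` gait cycles, each the template warped by the
#' configured ROM scales, hip-peak delay and knee swing deficit, with
#' per-cycle amplitude/phase/duration jitter and additive measurement noise.
#' Initial-contact events (0-based sample indices) mark every cycle start and
#' the final cycle end.  Output is fully determined by
#' `(template, effect, n_cycles, rate, seed)`.
#'
#' @param template a [gait_template()].
#' @param effect an [effect_config()].
#' @param n_cycles number of gait cycles (>= 2).
#' @param rate sampling rate in Hz (> 0); default 200.
#' @param seed integer seed for this trial.
#' @param subject_id,group identifiers carried into the output.
#' @return An object of class `angle_ts`: list with `subject_id`, `group`,
#'   `speed`, `rate`, `hip`, `knee` (degrees) and `events` (0-based
#'   initial-contact sample indices).
#' @examples
#' tr <- simulate_trial(gait_template("preferred"), effect_config(),
#'                      n_cycles = 4, seed = 7)
#' length(tr$events)  # 5: four cycle starts plus the final cycle end
#' @export
simulate_trial <- function(template, effect = effect_config(), n_cycles = 5L,
                           rate = 200, seed = 1L,
                           subject_id = "S01", group = "control") {
  stopifnot(inherits(template, "gait_template"), inherits(effect, "effect_config"))
  if (rate <= 0) stop("sampling rate must be positive")
  if (n_cycles < 2) stop("n_cycles must be >= 2")

  # refine the template onto a fine periodic grid for accurate resampling
  fine <- seq(0, 100, length.out = 401L)
  hip_t <- spline(template$grid, template$hip, xout = fine, method = "periodic")$y
  knee_t <- spline(template$grid, template$knee, xout = fine, method = "periodic")$y
  m_h <- mean(hip_t)
  m_k <- mean(knee_t)

  # hip-peak delay: warp the phase axis over the swing portion only
  if (effect$hip_peak_delay_pct > 0) {
    sw <- fine >= template$toe_off_pct
    p0 <- fine[sw][which.max(hip_t[sw])]
    src <- delay_warp_inverse(fine, template$toe_off_pct, p0,
                              effect$hip_peak_delay_pct)
    hip_t <- approx(fine, hip_t, xout = src, rule = 2)$y
  }
  knee_t <- knee_t - effect$knee_swing_deficit_deg * swing_bump(fine)

  dur0 <- if (is.na(effect$cycle_duration_s)) template$cycle_duration_s else
    effect$cycle_duration_s

  with_seed(seed, {
    durs <- dur0 * exp(rnorm(n_cycles, 0, effect$duration_jitter))
    amp_h <- pmax(0.1, 1 + rnorm(n_cycles, 0, effect$amp_noise_sd))
    amp_k <- pmax(0.1, 1 + rnorm(n_cycles, 0, effect$amp_noise_sd))
    dphase <- rnorm(n_cycles, 0, effect$phase_noise_sd)

    hip_out <- vector("list", n_cycles)
    knee_out <- vector("list", n_cycles)
    n_s <- pmax(3L, as.integer(round(durs * rate)))
    for (k in seq_len(n_cycles)) {
      phases <- seq(0, 100, length.out = n_s[k])
      at <- phases + dphase[k]
      h <- interp_periodic(fine, hip_t, at)
      q <- interp_periodic(fine, knee_t, at)
      hip_out[[k]] <- m_h + effect$hip_rom_scale * amp_h[k] * (h - m_h)
      knee_out[[k]] <- m_k + effect$knee_rom_scale * amp_k[k] * (q - m_k)
    }
    # one trailing sample: the initial contact closing the final cycle
    at0 <- dphase[n_cycles]
    hip_last <- m_h + effect$hip_rom_scale * amp_h[n_cycles] *
      (interp_periodic(fine, hip_t, at0) - m_h)
    knee_last <- m_k + effect$knee_rom_scale * amp_k[n_cycles] *
      (interp_periodic(fine, knee_t, at0) - m_k)

    hip <- c(unlist(hip_out), hip_last)
    knee <- c(unlist(knee_out), knee_last)
    if (effect$meas_noise_sd > 0) {
      hip <- hip + rnorm(length(hip), 0, effect$meas_noise_sd)
      knee <- knee + rnorm(length(knee), 0, effect$meas_noise_sd)
    }
    events <- as.integer(c(0L, cumsum(n_s)))
    structure(list(subject_id = subject_id, group = group,
                   speed = template$speed, rate = rate,
                   hip = hip, knee = knee, events = events),
              class = "angle_ts")
  })
}

#' @export
print.angle_ts <- function(x, ...) {
  cat(sprintf("Angle time series: subject %s (%s, %s speed)\n",
              x$subject_id, x$group, x$speed))
  cat(sprintf("  %d samples at %g Hz, %d initial-contact events (%d cycles)\n",
              length(x$hip), x$rate, length(x$events), length(x$events) - 1L))
  invisible(x)
}

#' Per-speed effect configurations emulating a case-control gait study
#'
#' Returns the default effect configurations for a three-group cohort
#' (healthy controls, Parkinson's disease on medication, and a paired
#' off-medication subset).  Joint ROM multipliers are the ratios of the
#' group-median ROMs to the control medians at each speed, so simulated
#' group medians track the clinical pattern: markedly reduced knee ROM in
#' both PD groups at all speeds, reduced hip ROM mainly at fast speed, and a
#' delayed swing-phase hip-flexion peak in PD.
#'
#' @param ... named arguments forwarded to every [effect_config()] call
#'   (e.g. `amp_noise_sd`), overriding the shared noise defaults.
#' @return Named list `group -> speed -> effect_config`.
#' @export
study_effects <- function(...) {
  mk <- function(h, k, delay = 0) {
    effect_config(hip_rom_scale = h, knee_rom_scale = k,
                  hip_peak_delay_pct = delay, ...)
  }
  list(
    control = list(fast = mk(1, 1), preferred = mk(1, 1), slow = mk(1, 1)),
    pd_on = list(fast = mk(41 / 46, 55 / 64, delay = 4),
                 preferred = mk(36 / 41, 54 / 62, delay = 4),
                 slow = mk(30 / 33, 50 / 59, delay = 4)),
    pd_off = list(fast = mk(37 / 46, 52 / 64, delay = 4),
                  preferred = mk(36 / 41, 55 / 62, delay = 4),
                  slow = mk(31 / 33, 45 / 59, delay = 4))
  )
}

#' Cohort design for the synthetic generator
#'
#' @param n_per_group subjects per group (>= 2); default 29, the size of the
#'   emulated study arms.
#' @param n_off size of the paired off-medication subset (first `n_off`
#'   PD subjects, re-measured); default 8.  Ignored unless `"pd_off"` is in
#'   `groups`.
#' @param groups subset of `c("control", "pd_on", "pd_off")`.
#' @param speeds subset of `c("slow", "preferred", "fast")`.
#' @param n_cycles_per_trial gait cycles per trial (>= 2); default 5,
#'   matching a short straight walkway bout.
#' @param rate sampling rate in Hz; default 200.
#' @param seed root seed; per-trial seeds are derived deterministically.
#' @param effects `group -> speed -> effect_config` list; default
#'   [study_effects()].
#' @param subject_sd SD of the log-normal between-subject ROM multiplier
#'   (shared by the paired on/off assessments of a PD subject).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 29L, n_off = 8L,
                          groups = c("control", "pd_on", "pd_off"),
                          speeds = c("slow", "preferred", "fast"),
                          n_cycles_per_trial = 5L, rate = 200, seed = 1L,
                          effects = study_effects(), subject_sd = 0.07) {
  groups <- match.arg(groups, c("control", "pd_on", "pd_off"), several.ok = TRUE)
  speeds <- match.arg(speeds, c("slow", "preferred", "fast"), several.ok = TRUE)
  stopifnot(n_per_group >= 2, n_cycles_per_trial >= 2, rate > 0,
            n_off >= 0, n_off <= n_per_group, subject_sd >= 0)
  if (length(groups) == 0 || length(speeds) == 0)
    stop("at least one group and one speed required")
  structure(list(n_per_group = as.integer(n_per_group), n_off = as.integer(n_off),
                 groups = groups, speeds = speeds,
                 n_cycles_per_trial = as.integer(n_cycles_per_trial),
                 rate = rate, seed = as.integer(seed), effects = effects,
                 subject_sd = subject_sd),
            class = "cohort_config")
}

#' Simulate a full synthetic cohort
#'
#' One trial per subject and speed.  The off-medication group is a paired
#' subset: its subjects reuse the identity and between-subject baseline ROM
#' multipliers of the first `n_off` on-medication PD subjects, so paired
#' on/off comparisons are meaningful.  The root seed fully determines the
#' output; per-trial seeds are derived from (group, subject, speed).
#'
#' @param config a [cohort_config()].
#' @return List with `trials` (list of [simulate_trial()] outputs) and
#'   `manifest` (data frame: `subject_id`, `group`, `speed`, `seed`,
#'   `n_cycles`).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_per_group = 2, n_off = 0,
#'   groups = c("control", "pd_on"), speeds = c("preferred", "fast"),
#'   n_cycles_per_trial = 2, seed = 42))
#' nrow(coh$manifest)  # 8
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  templates <- lapply(setNames(config$speeds, config$speeds), gait_template)
  trials <- list()
  rows <- list()
  for (grp in config$groups) {
    n_subj <- if (grp == "pd_off") config$n_off else config$n_per_group
    if (n_subj == 0) next
    base_grp <- if (grp == "pd_off") "pd_on" else grp  # shared subject identity
    for (s in seq_len(n_subj)) {
      sid <- sprintf("%s%02d", if (base_grp == "control") "C" else "P", s)
      # between-subject baseline: shared across speeds and on/off sessions
      bseed <- child_seed(config$seed, "subject", base_grp, s)
      base <- with_seed(bseed, exp(rnorm(2, 0, config$subject_sd)))
      for (sp in config$speeds) {
        eff <- config$effects[[grp]][[sp]]
        if (is.null(eff)) stop("no effect_config for ", grp, "/", sp)
        eff2 <- eff
        eff2$hip_rom_scale <- eff$hip_rom_scale * base[1]
        eff2$knee_rom_scale <- eff$knee_rom_scale * base[2]
        tseed <- child_seed(config$seed, "trial", grp, s, sp)
        key <- paste(sid, grp, sp, sep = "_")
        trials[[key]] <- simulate_trial(templates[[sp]], eff2,
                                        n_cycles = config$n_cycles_per_trial,
                                        rate = config$rate, seed = tseed,
                                        subject_id = sid, group = grp)
        rows[[key]] <- data.frame(subject_id = sid, group = grp, speed = sp,
                                  seed = tseed,
                                  n_cycles = config$n_cycles_per_trial,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(trials = trials, manifest = manifest)
}
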