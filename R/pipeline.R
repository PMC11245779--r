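# Orchestration: cohort-level metric tables, speed-adaptation ratio tables,
# group summary tables, file interchange (long-format angle CSV + events
# JSON + manifest CSV) and the end-to-end
# simulate -> prep -> metrics -> SPM -> stats pipeline.

#' Per-trial metric table for a cohort
#'
#' Runs [prep_trial()] and [trial_metrics()] on every trial and binds the
#' results into a tidy table keyed by subject, group and speed.
#'
#' @param trials list of [angle_ts()] trials.
#' @param n_points normalization grid size (default 101).
#' @param acc_variant,ssd_convention passed to [trial_metrics()].
#' @return Data frame: `subject_id`, `group`, `speed`, `rom_hip`,
#'   `rom_knee`, `acc`, `ssd`, `min_pct`, `min_mag`, `max_pct`, `max_mag`.
#' @export
cohort_metrics <- function(trials, n_points = 101L,
                           acc_variant = "resultant",
                           ssd_convention = "rms") {
  rows <- lapply(trials, function(ts) {
    cycles <- prep_trial(ts, n_points = n_points, center = TRUE)
    cbind(data.frame(subject_id = ts$subject_id, group = ts$group,
                     speed = ts$speed, stringsAsFactors = FALSE),
          trial_metrics(cycles, acc_variant = acc_variant,
                        ssd_convention = ssd_convention))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-speed adaptation ratios for every subject
#'
#' For each subject and group, computes [speed_adaptation_ratio()] for every
#' faster/slower speed pair present (fast vs preferred, fast vs slow,
#' preferred vs slow).
#'
#' @param metrics a table from [cohort_metrics()].
#' @return Data frame keyed by `subject_id`, `group`, `comparison` with
#'   `ratio_min`, `ratio_max`, `ratio_of_ratios`.
#' @export
speed_ratios <- function(metrics) {
  ord <- c(fast = 3, preferred = 2, slow = 1)
  pairs <- list(c("fast", "preferred"), c("fast", "slow"),
                c("preferred", "slow"))
  rows <- list()
  for (key in unique(paste(metrics$subject_id, metrics$group, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- metrics[metrics$subject_id == parts[1] & metrics$group == parts[2], ]
    for (p in pairs) {
      a <- sub[sub$speed == p[1], ]
      b <- sub[sub$speed == p[2], ]
      if (nrow(a) == 1 && nrow(b) == 1) {
        r <- speed_adaptation_ratio(a, b, paste(p, collapse = "_vs_"))
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(subject_id = parts[1], group = parts[2],
                           stringsAsFactors = FALSE), r)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group summary table of cohort metrics
#'
#' Median (range) per metric, group and speed — the layout of a clinical
#' kinematics summary table — plus, per metric and group, the within-group
#' three-condition omnibus p-value (when all three speeds are present) and,
#' per metric and speed, the two-group p-value against the control group.
#'
#' @param metrics a table from [cohort_metrics()].
#' @param alpha significance level for the omnibus gates (default 0.05).
#' @return Data frame with one row per metric x group x speed.
#' @export
summarize_metrics <- function(metrics, alpha = 0.05) {
  vars <- c("rom_hip", "rom_knee", "acc", "ssd")
  vars <- intersect(vars, names(metrics))
  groups <- unique(metrics$group)
  speeds <- intersect(c("fast", "preferred", "slow"), unique(metrics$speed))
  rows <- list()
  for (v in vars) {
    for (g in groups) {
      sub <- metrics[metrics$group == g, ]
      omni_p <- NA_real_
      if (length(speeds) == 3) {
        wide <- sapply(speeds, function(sp) {
          x <- sub[sub$speed == sp, ]
          x[[v]][match(unique(sub$subject_id), x$subject_id)]
        })
        wide <- wide[complete.cases(wide), , drop = FALSE]
        if (nrow(wide) >= 5) {
          omni_p <- tryCatch(compare_three_conditions(wide, alpha)$p_value,
                             error = function(e) NA_real_)
        }
      }
      for (sp in speeds) {
        x <- sub[[v]][sub$speed == sp]
        vs_control_p <- NA_real_
        if (g != "control" && "control" %in% groups) {
          ctrl <- metrics[[v]][metrics$group == "control" & metrics$speed == sp]
          if (length(ctrl) >= 3 && length(x) >= 3) {
            vs_control_p <- tryCatch(compare_two_groups(x, ctrl)$p_value,
                                     error = function(e) NA_real_)
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          metric = v, group = g, speed = sp,
          median = median(x), min = min(x), max = max(x),
          display = sprintf("%.2f (%.2f-%.2f)", median(x), min(x), max(x)),
          within_group_p = omni_p, vs_control_p = vs_control_p,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subject mean curves for continuum analysis
#'
#' Builds the curve matrix that SPM consumes: for every subject of one
#' group at one speed, the point-wise mean of the trial's time-normalized
#' cycles for one joint (optionally mean-centered and/or
#' amplitude-normalized).
#'
#' @param trials list of [angle_ts()] trials.
#' @param group,speed,joint which slice of the cohort to extract
#'   (`joint` is `"hip"` or `"knee"`).
#' @param n_points grid size (default 101).
#' @param center mean-center each cycle before averaging (default `FALSE`;
#'   amplitude comparisons use raw angles).
#' @param spatial amplitude-normalize each cycle (see
#'   [spatial_normalize()]) for temporal comparisons.
#' @param spatial_method `"minmax"` or `"zscore"`.
#' @return Matrix with one row per subject (rownames = subject ids), or
#'   `NULL` if the slice is empty.
#' @export
subject_mean_curves <- function(trials, group, speed, joint,
                                n_points = 101L, center = FALSE,
                                spatial = FALSE, spatial_method = "minmax") {
  sel <- Filter(function(ts) ts$group == group && ts$speed == speed, trials)
  if (!length(sel)) return(NULL)
  sids <- vapply(sel, `[[`, character(1), "subject_id")
  M <- t(vapply(sel, function(ts) {
    cycles <- prep_trial(ts, n_points = n_points, center = center)
    if (spatial) cycles <- lapply(cycles, spatial_normalize,
                                  method = spatial_method)
    rowMeans(vapply(cycles, `[[`, numeric(n_points), joint))
  }, numeric(n_points)))
  rownames(M) <- sids
  M
}

#' Write a cohort to its interchange format
#'
#' One long-format CSV per trial (`subject_id, group, speed, time_s,
#' hip_deg, knee_deg`), a sidecar `events.json` mapping trial file names to
#' 0-based initial-contact sample indices, and a `manifest.csv` with columns
#' `subject_id, group, speed, trial_file, seed`.
#'
#' @param cohort list with `trials` and `manifest` (see [simulate_cohort()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "trials"), recursive = TRUE, showWarnings = FALSE)
  events <- list()
  files <- character(length(cohort$trials))
  for (i in seq_along(cohort$trials)) {
    ts <- cohort$trials[[i]]
    fn <- paste0(names(cohort$trials)[i], ".csv")
    files[i] <- fn
    n <- length(ts$hip)
    write.csv(data.frame(subject_id = ts$subject_id, group = ts$group,
                         speed = ts$speed, time_s = (seq_len(n) - 1) / ts$rate,
                         hip_deg = ts$hip, knee_deg = ts$knee),
              file.path(dir, "trials", fn), row.names = FALSE)
    events[[fn]] <- ts$events
  }
  jsonlite::write_json(events, file.path(dir, "events.json"))
  manifest <- cohort$manifest
  manifest$trial_file <- files
  manifest <- manifest[, c("subject_id", "group", "speed", "trial_file", "seed")]
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from its interchange format
#'
#' @param dir directory written by [write_cohort()].
#' @return List with `trials` and `manifest`.
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  events <- jsonlite::read_json(file.path(dir, "events.json"),
                                simplifyVector = TRUE)
  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    fn <- manifest$trial_file[i]
    d <- read.csv(file.path(dir, "trials", fn), stringsAsFactors = FALSE)
    rate <- 1 / median(diff(d$time_s))
    angle_ts(hip = d$hip_deg, knee = d$knee_deg, events = events[[fn]],
             rate = rate, subject_id = d$subject_id[1], group = d$group[1],
             speed = d$speed[1])
  })
  names(trials) <- sub("\\.csv$", "", manifest$trial_file)
  list(trials = trials, manifest = manifest)
}

#' Pipeline run configuration
#'
#' @param simulate a [cohort_config()] to generate inputs, or `NULL` to read
#'   them from `input_dir`.
#' @param input_dir directory in the [write_cohort()] interchange format.
#' @param out_dir output directory.
#' @param n_points normalization grid size.
#' @param alpha significance level.
#' @param ssd_convention `"rms"` or `"sum"`.
#' @param acc_variant `"resultant"` or `"consecutive"`.
#' @param spatial_norm `"minmax"` or `"zscore"`.
#' @param qc a [qc_rules()] list.
#' @param make_plots write SPM figures as PNG files.
#' @param seed root seed recorded in the run manifest (and used for
#'   simulation when `simulate` carries no seed of its own).
#' @return Object of class `run_config`.
#' @export
run_config <- function(simulate = NULL, input_dir = NULL, out_dir,
                       n_points = 101L, alpha = 0.05,
                       ssd_convention = c("rms", "sum"),
                       acc_variant = c("resultant", "consecutive"),
                       spatial_norm = c("minmax", "zscore"),
                       qc = qc_rules(), make_plots = FALSE, seed = 1L) {
  if (is.null(simulate) && is.null(input_dir))
    stop("config error: either a simulate block or an input_dir is required")
  if (!is.null(simulate) && !is.null(input_dir))
    stop("config error: simulate block and input_dir are mutually exclusive")
  structure(list(simulate = simulate, input_dir = input_dir,
                 out_dir = out_dir, n_points = as.integer(n_points),
                 alpha = alpha, ssd_convention = match.arg(ssd_convention),
                 acc_variant = match.arg(acc_variant),
                 spatial_norm = match.arg(spatial_norm), qc = qc,
                 make_plots = isTRUE(make_plots), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> QC -> cycle prep -> cyclogram metrics -> SPM ->
#' scalar statistics -> report files.  Outputs: `metrics.csv`, `ratios.csv`,
#' `summary_table.csv`, `spm/*.json` (and `.png` if requested),
#' `stats.json`, and `run_manifest.json` recording the config echo, its
#' hash, and per-stage trial counts.  Re-running with the same config and
#' seed reproduces the outputs; a directory holding outputs of a different
#' config hash is refused.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `metrics`, `ratios`, `summary`, `spm`,
#'   `stats` and `counts`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(unclass(config)[setdiff(names(unclass(config)),
                                              c("out_dir", "make_plots"))])
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  mf_path <- file.path(out, "run_manifest.json")
  if (file.exists(mf_path)) {
    prev <- jsonlite::read_json(mf_path)
    if (!identical(prev$config_hash, hash))
      stop("output directory holds results of a different configuration; refusing to mix")
  }

  cohort <- if (!is.null(config$simulate)) {
    simulate_cohort(config$simulate)
  } else read_cohort(config$input_dir)
  trials_in <- length(cohort$trials)
  message(sprintf("pipeline: %d trials in", trials_in))

  qc_res <- lapply(cohort$trials, qc_trial, rules = config$qc)
  keep <- vapply(qc_res, `[[`, logical(1), "keep")
  excluded <- names(cohort$trials)[!keep]
  if (length(excluded))
    message(sprintf("pipeline: %d trial(s) excluded by QC: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  trials <- cohort$trials[keep]

  metrics <- cohort_metrics(trials, n_points = config$n_points,
                            acc_variant = config$acc_variant,
                            ssd_convention = config$ssd_convention)
  write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)

  ratios <- speed_ratios(metrics)
  if (!is.null(ratios))
    write.csv(ratios, file.path(out, "ratios.csv"), row.names = FALSE)

  summary_tab <- summarize_metrics(metrics, alpha = config$alpha)
  write.csv(summary_tab, file.path(out, "summary_table.csv"), row.names = FALSE)

  # SPM comparisons
  spm_dir <- file.path(out, "spm")
  dir.create(spm_dir, showWarnings = FALSE)
  groups <- unique(metrics$group)
  speeds <- unique(metrics$speed)
  spm_results <- list()
  run_one <- function(name, YA, YB, paired = FALSE) {
    if (is.null(YA) || is.null(YB)) return()
    if (paired) {
      common <- intersect(rownames(YA), rownames(YB))
      if (length(common) < 3) return()  # df >= 2 needed for the RFT threshold
      res <- spm_ttest_paired(YA[common, , drop = FALSE],
                              YB[common, , drop = FALSE],
                              alpha = config$alpha)
    } else {
      if (nrow(YA) < 2 || nrow(YB) < 2) return()
      res <- spm_ttest2(YA, YB, alpha = config$alpha)
    }
    spm_results[[name]] <<- res
    spm_to_json(res, file.path(spm_dir, paste0(name, ".json")))
    if (config$make_plots) {
      png(file.path(spm_dir, paste0(name, ".png")), width = 700, height = 450)
      plot(res, main = name)
      dev.off()
    }
  }
  for (sp in speeds) {
    for (joint in c("hip", "knee")) {
      if (all(c("control", "pd_on") %in% groups)) {
        YA <- subject_mean_curves(trials, "control", sp, joint, config$n_points)
        YB <- subject_mean_curves(trials, "pd_on", sp, joint, config$n_points)
        run_one(sprintf("ttest2_control_vs_pd_on_%s_%s", sp, joint), YA, YB)
        SA <- subject_mean_curves(trials, "control", sp, joint, config$n_points,
                                  spatial = TRUE,
                                  spatial_method = config$spatial_norm)
        SB <- subject_mean_curves(trials, "pd_on", sp, joint, config$n_points,
                                  spatial = TRUE,
                                  spatial_method = config$spatial_norm)
        run_one(sprintf("ttest2_spatial_control_vs_pd_on_%s_%s", sp, joint),
                SA, SB)
      }
      if (all(c("pd_on", "pd_off") %in% groups)) {
        YA <- subject_mean_curves(trials, "pd_on", sp, joint, config$n_points)
        YB <- subject_mean_curves(trials, "pd_off", sp, joint, config$n_points)
        run_one(sprintf("paired_pd_on_vs_pd_off_%s_%s", sp, joint),
                YA, YB, paired = TRUE)
      }
    }
  }

  # scalar statistics
  stats_list <- list()
  for (v in c("rom_hip", "rom_knee", "acc", "ssd")) {
    for (sp in speeds) {
      if (all(c("control", "pd_on") %in% groups)) {
        a <- metrics[[v]][metrics$group == "control" & metrics$speed == sp]
        b <- metrics[[v]][metrics$group == "pd_on" & metrics$speed == sp]
        if (length(a) >= 3 && length(b) >= 3) {
          rep_ <- tryCatch(compare_two_groups(a, b, config$alpha),
                           error = function(e) NULL)
          if (!is.null(rep_))
            stats_list[[sprintf("%s_%s_control_vs_pd_on", v, sp)]] <-
              unclass(rep_)[c("test_name", "statistic", "p_value",
                              "normality_gate")]
        }
      }
      if (all(c("pd_on", "pd_off") %in% groups)) {
        on_m <- metrics[metrics$group == "pd_on" & metrics$speed == sp, ]
        off_m <- metrics[metrics$group == "pd_off" & metrics$speed == sp, ]
        common <- intersect(on_m$subject_id, off_m$subject_id)
        if (length(common) >= 5) {
          rep_ <- compare_paired(on_m[[v]][match(common, on_m$subject_id)],
                                 off_m[[v]][match(common, off_m$subject_id)],
                                 config$alpha)
          stats_list[[sprintf("%s_%s_pd_on_vs_pd_off", v, sp)]] <-
            unclass(rep_)[c("test_name", "statistic", "p_value")]
        }
      }
    }
  }
  jsonlite::write_json(stats_list, file.path(out, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  counts <- list(trials_in = trials_in, trials_excluded = length(excluded),
                 trials_analyzed = length(trials))
  manifest <- list(package_version = as.character(utils::packageVersion("cyclokin")),
                   config_hash = hash, seed = config$seed,
                   counts = counts, excluded_trials = excluded,
                   config = list(n_points = config$n_points,
                                 alpha = config$alpha,
                                 ssd_convention = config$ssd_convention,
                                 acc_variant = config$acc_variant,
                                 spatial_norm = config$spatial_norm))
  jsonlite::write_json(manifest, mf_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  message(sprintf("pipeline: %d trials analyzed", counts$trials_analyzed))
  invisible(list(metrics = metrics, ratios = ratios, summary = summary_tab,
                 spm = spm_results, stats = stats_list, counts = counts))
}
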