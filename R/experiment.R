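# End-to-end orchestration: a single configuration object, session
# simulation across observers/conditions, tidy threshold tables with
# session aggregation and exclusion decisions, and the trial-level gaze
# pipeline (simulate -> detect -> QC -> filter -> attribute).

#' Experiment configuration
#'
#' Bundles every knob of the simulated experiment; all randomness derives
#' from the explicit `seed` (no wall-clock seeding).
#'
#' @param seed Master seed.
#' @param conditions Conditions to run.
#' @param profile Interval-duration profile (`"exp1"` or `"exp2"`).
#' @param n_observers Simulated observers.
#' @param sessions_per_condition Sessions per observer and condition.
#' @param cct,n_steps Illuminant-series parameters.
#' @param gain_amplitude Illumination gain-field amplitude.
#' @param gaze A [gaze_profile()] (generator knobs).
#' @param detector A [detector_params()].
#' @param qc_max_missing,qc_max_noise QC exclusion fractions.
#' @param display_deg Display extent in degrees.
#' @param out_dir Output directory for the analysis drivers.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1,
                              conditions = c("fixed", "shuffled"),
                              profile = "exp1",
                              n_observers = 10,
                              sessions_per_condition = 2,
                              cct = 6700, n_steps = 50,
                              gain_amplitude = 0.15,
                              gaze = gaze_profile(),
                              detector = detector_params(),
                              qc_max_missing = 0.05,
                              qc_max_noise = 0.20,
                              display_deg = c(24, 20),
                              out_dir = "results") {
  structure(as.list(environment()), class = "experiment_config")
}

#' Simulate sessions for a set of observers
#'
#' Runs every observer through `sessions_per_condition` sessions of each
#' condition. Observers are a named list of `sim_observer`s; thresholds
#' drawn per observer govern responses through [respond()].
#'
#' @param observers Named list of `sim_observer` objects.
#' @param series An `illuminant_series`.
#' @param config An [experiment_config()].
#' @return List of `session_log`s.
#' @export
simulate_experiment <- function(observers, series, config = experiment_config()) {
  scfg <- session_config(config$profile)
  logs <- list()
  i <- 0
  for (obs_id in names(observers)) {
    for (cond in config$conditions) {
      for (ss in seq_len(config$sessions_per_condition)) {
        i <- i + 1
        logs[[i]] <- run_session(
          observers[[obs_id]], cond, series, scfg,
          seed = derive_seed(config$seed, match(obs_id, names(observers)),
                             match(cond, config$conditions), ss),
          observer_id = obs_id, session = ss
        )
      }
    }
  }
  logs
}

#' Tidy session-threshold table
#'
#' @param logs List of `session_log`s.
#' @param series The `illuminant_series`.
#' @return Data frame: one row per observer x condition x session x
#'   direction (see [session_thresholds()]).
#' @export
threshold_table <- function(logs, series) {
  do.call(rbind, lapply(logs, session_thresholds, series = series))
}

#' Aggregate session thresholds per observer, condition and direction
#'
#' Applies the out-of-range substitution (maximal actual test Delta E of the
#' direction) and averages the two sessions; directions out of range in both
#' sessions carry the sentinel `NA` with `both_out_of_range = TRUE`.
#'
#' @param tbl Output of [threshold_table()].
#' @param series The `illuminant_series`.
#' @return Data frame: `observer`, `condition`, `direction`, `threshold`,
#'   `substituted`, `both_out_of_range`.
#' @export
aggregate_threshold_table <- function(tbl, series) {
  keys <- unique(tbl[, c("observer", "condition", "direction")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- tbl[tbl$observer == keys$observer[i] &
               tbl$condition == keys$condition[i] &
               tbl$direction == keys$direction[i], ]
    sub <- sub[order(sub$session), ]
    if (nrow(sub) != 2) {
      stop("aggregation expects exactly two sessions per cell", call. = FALSE)
    }
    agg <- aggregate_sessions(sub$threshold[1], sub$threshold[2],
                              sub$in_range[1], sub$in_range[2],
                              max_test_delta_e(series, keys$direction[i]))
    data.frame(observer = keys$observer[i], condition = keys$condition[i],
               direction = keys$direction[i], threshold = agg$threshold,
               substituted = agg$substituted,
               both_out_of_range = agg$both_out_of_range)
  })
  do.call(rbind, rows)
}

#' Exclusion decision per observer
#'
#' @param tbl Output of [threshold_table()] covering all of each observer's
#'   cells.
#' @return Data frame: `observer`, `decision`.
#' @export
observer_decisions <- function(tbl) {
  obs <- unique(tbl$observer)
  data.frame(observer = obs,
             decision = vapply(obs, function(o) {
               apply_exclusions(tbl[tbl$observer == o, ])
             }, character(1)))
}

#' Simulate and analyze gaze for a block of trials
#'
#' For each trial builds the three interval scenes (one canonical assignment
#' everywhere in the fixed condition; fresh assignments per interval in the
#' shuffled condition), simulates the gaze stream, detects fixations, applies
#' trial QC, filters and attributes the fixations.
#'
#' @param n_trials Number of trials.
#' @param condition `"fixed"` or `"shuffled"`.
#' @param refl Reflectance set (names index assignments).
#' @param grid Tile grid.
#' @param config An [experiment_config()] (gaze profile, detector, QC).
#' @param seed Integer seed.
#' @return List: `fixations` (attributed, kept trials, with `trial` column),
#'   `qc` (per-trial decisions), `truth` (planted fixations per trial),
#'   `n_kept`.
#' @export
simulate_fixation_trials <- function(n_trials, condition, refl, grid,
                                     config = experiment_config(profile = "exp2"),
                                     seed = 1) {
  scfg <- session_config(config$profile)
  refl_names <- names(refl)
  canonical <- assign_reflectances(grid, length(refl),
                                   seed = derive_seed(seed, 0))
  fx_all <- list(); qc_all <- list(); truth_all <- list()
  for (tr in seq_len(n_trials)) {
    scenes <- lapply(1:3, function(k) {
      asg <- if (condition == "fixed") canonical
             else assign_reflectances(grid, length(refl),
                                      seed = derive_seed(seed, tr, k))
      scene_spec(sprintf("t%d_i%d", tr, k), condition,
                 if (k == 1) "target" else "test", assignment = asg)
    })
    st <- simulate_gaze(config$gaze, scfg, scenes, grid, refl_names,
                        seed = derive_seed(seed, tr, 99))
    det <- detect_fixations(st, config$detector)
    qc <- qc_trial(st, det, config$display_deg,
                   config$qc_max_missing, config$qc_max_noise)
    qc_all[[tr]] <- data.frame(trial = tr, keep = qc$keep,
                               reason = if (is.na(qc$reason)) "" else qc$reason)
    if (!is.null(st$truth)) {
      tru <- st$truth; tru$trial <- tr
      truth_all[[tr]] <- tru
    }
    if (qc$keep) {
      fx <- filter_fixations(det$fixations, config$display_deg)
      fx <- attribute_fixations(fx, scenes, grid, refl_names)
      if (nrow(fx)) {
        fx$trial <- tr
        fx_all[[length(fx_all) + 1]] <- fx
      }
    }
  }
  fixations <- if (length(fx_all)) {
    do.call(rbind, c(fx_all, list(make.row.names = FALSE)))
  } else NULL
  list(fixations = fixations,
       qc = do.call(rbind, c(qc_all, list(make.row.names = FALSE))),
       truth = if (length(truth_all)) {
         do.call(rbind, c(truth_all, list(make.row.names = FALSE)))
       } else NULL,
       n_kept = sum(vapply(qc_all, function(q) q$keep, logical(1))))
}
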