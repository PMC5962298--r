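# Synthetic 1000 Hz gaze traces over the three stimulus intervals of a
# trial: planned fixations connected by minimum-jerk saccades, with blinks
# (invalid runs flanked by brief high-velocity artifacts), random sample
# dropouts and additive position noise. The planner's strategy knobs control
# whether comparison-interval fixations reuse target-interval screen
# locations or track the reflectances fixated in the target interval — the
# two observer strategies the overlap statistics disentangle.

#' Gaze generator profile
#'
#' @param mean_fix_ms Mean planned fixation duration (gamma-distributed,
#'   truncated at `min_fix_ms`).
#' @param min_fix_ms Minimum planned fixation duration.
#' @param location_reuse Probability that a comparison-interval fixation
#'   reuses a target-interval screen location.
#' @param reflectance_tracking Probability that a comparison-interval
#'   fixation lands on a tile carrying a reflectance fixated in the target
#'   interval. `location_reuse + reflectance_tracking <= 1`; the remainder is
#'   fresh exploration.
#' @param spread_deg SD of the Gaussian scatter of fresh fixation locations
#'   around the image center.
#' @param blink_rate Blinks per second.
#' @param blink_ms Blink duration (invalid run).
#' @param dropout_rate Per-sample probability of an isolated invalid sample.
#' @param noise_sd Additive isotropic position noise SD in degrees.
#' @return List of class `gaze_profile`.
#' @export
gaze_profile <- function(mean_fix_ms = 250, min_fix_ms = 120,
                         location_reuse = 0.5, reflectance_tracking = 0,
                         spread_deg = 3, blink_rate = 0.1, blink_ms = 120,
                         dropout_rate = 0.001, noise_sd = 0.05) {
  stopifnot(location_reuse >= 0, reflectance_tracking >= 0,
            location_reuse + reflectance_tracking <= 1,
            mean_fix_ms > 0, min_fix_ms >= 0, spread_deg >= 0,
            blink_rate >= 0, dropout_rate >= 0, dropout_rate <= 1,
            noise_sd >= 0)
  structure(as.list(environment()), class = "gaze_profile")
}

# main-sequence-like saccade kinematics: peak velocity (deg/s) from
# amplitude, floored so even the smallest planned saccades stand well clear
# of the detector's adapted velocity thresholds
saccade_peak_velocity <- function(amplitude) pmax(150, 75 * amplitude^0.7)

# minimum-jerk position profile on [0, 1]
minjerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Simulate a trial's gaze stream
#'
#' Generates samples for the three stimulus intervals (target, comparison 1,
#' comparison 2) at `hz`, separated by blank gaps taken from the session
#' config. Returns the raw sample stream plus the planted ground truth.
#'
#' @param profile A [gaze_profile()].
#' @param config A [session_config()] (interval durations).
#' @param scenes Optional list of three [scene_spec()]s (target, comp1,
#'   comp2) enabling tile-aware strategies; `NULL` for free-field gaze.
#' @param grid Tile grid (required with `scenes`).
#' @param refl_names Reflectance names indexing scene assignments.
#' @param hz Sampling rate.
#' @param seed Integer seed.
#' @return List of class `gaze_stream`: `samples` (data frame `t_ms`,
#'   `x_deg`, `y_deg`, `valid`, `interval`), `intervals` (data frame with
#'   onset/offset per interval), `truth` (planted fixations: `interval`,
#'   `onset`, `offset`, `x`, `y`, `duration`).
#' @export
simulate_gaze <- function(profile, config = session_config("exp2"),
                          scenes = NULL, grid = NULL, refl_names = NULL,
                          hz = 1000, seed = 1) {
  with_seed(seed, simulate_gaze_impl(profile, config, scenes, grid, refl_names, hz))
}

simulate_gaze_impl <- function(profile, config, scenes, grid, refl_names, hz) {
  iv <- config$intervals_ms
  durs <- c(target = unname(iv["target"]), comp1 = unname(iv["comparison"]),
            comp2 = unname(iv["comparison"]))
  blank <- unname(iv["blank"])
  onsets <- c(0, cumsum(durs[-3] + blank))
  names(onsets) <- names(durs)

  # tile-aware position pickers
  pick_fresh <- function(k) {
    if (!is.null(scenes) && !is.null(grid)) {
      ids <- sample.int(nrow(grid), k, replace = TRUE)
      cbind(grid$x[ids] + stats::rnorm(k, sd = 0.3),
            grid$y[ids] + stats::rnorm(k, sd = 0.3))
    } else {
      cbind(stats::rnorm(k, sd = profile$spread_deg),
            stats::rnorm(k, sd = profile$spread_deg))
    }
  }
  tiles_of_reflectances <- function(spec, wanted) {
    which(refl_names[spec$assignment] %in% wanted)
  }

  plan_interval <- function(name, target_plan) {
    dur <- durs[[name]]
    fixes <- list()
    t <- 0
    prev <- NULL
    while (TRUE) {
      d <- max(profile$min_fix_ms,
               stats::rgamma(1, shape = 4, scale = profile$mean_fix_ms / 4))
      if (t + profile$min_fix_ms > dur) break
      d <- min(d, dur - t)
      u <- stats::runif(1)
      if (name != "target" && u < profile$location_reuse &&
          nrow(target_plan) > 0) {
        i <- sample.int(nrow(target_plan), 1)
        pos <- c(target_plan$x[i], target_plan$y[i])
      } else if (name != "target" && !is.null(scenes) &&
                 u < profile$location_reuse + profile$reflectance_tracking &&
                 nrow(target_plan) > 0) {
        spec <- scenes[[match(name, c("target", "comp1", "comp2"))]]
        tgt_spec <- scenes[[1]]
        fixated_refl <- unique(refl_names[tgt_spec$assignment[
          stats::na.omit(locate_tile(grid, target_plan$x, target_plan$y))]])
        cand <- tiles_of_reflectances(spec, fixated_refl)
        if (length(cand)) {
          id <- resample(cand, 1)
          pos <- c(grid$x[id], grid$y[id])
        } else pos <- pick_fresh(1)
      } else {
        pos <- pick_fresh(1)
      }
      last <- length(fixes)
      if (last > 0 &&
          sqrt((pos[1] - fixes[[last]]$x)^2 +
               (pos[2] - fixes[[last]]$y)^2) < 0.5) {
        # a re-fixation of (essentially) the same spot is one longer fixation
        fixes[[last]]$duration <- fixes[[last]]$duration +
          (t - (fixes[[last]]$onset + fixes[[last]]$duration)) + d
      } else {
        fixes[[last + 1]] <- data.frame(x = pos[1], y = pos[2],
                                        onset = t, duration = d)
      }
      t <- t + d
      if (t >= dur) break
      # saccade to the next fixation costs time
      amp_guess <- 4
      t <- t + 1000 * 1.875 * amp_guess / saccade_peak_velocity(amp_guess)
      prev <- pos
    }
    do.call(rbind, fixes)
  }

  target_plan <- plan_interval("target", data.frame())
  plans <- list(target = target_plan,
                comp1 = plan_interval("comp1", target_plan),
                comp2 = plan_interval("comp2", target_plan))

  all_samples <- list()
  truth <- list()
  for (name in names(durs)) {
    dur <- durs[[name]]
    n <- round(dur * hz / 1000)
    tt <- seq_len(n) - 1 # ms within interval at 1000 Hz
    x <- numeric(n); y <- numeric(n)
    plan <- plans[[name]]
    # lay down fixations and connecting saccades
    prev_end <- NULL
    cursor <- if (!is.null(plan) && nrow(plan)) plan$x[1] else 0
    pos_x <- rep(if (!is.null(plan) && nrow(plan)) plan$x[1] else 0, n)
    pos_y <- rep(if (!is.null(plan) && nrow(plan)) plan$y[1] else 0, n)
    if (!is.null(plan) && nrow(plan)) {
      for (i in seq_len(nrow(plan))) {
        i0 <- max(1, round(plan$onset[i] * hz / 1000) + 1)
        i1 <- min(n, round((plan$onset[i] + plan$duration[i]) * hz / 1000))
        if (i0 > n) break
        pos_x[i0:n] <- plan$x[i]; pos_y[i0:n] <- plan$y[i]
        if (i > 1) {
          # minimum-jerk saccade from previous fixation end to this onset
          px <- plan$x[i - 1]; py <- plan$y[i - 1]
          amp <- sqrt((plan$x[i] - px)^2 + (plan$y[i] - py)^2)
          if (amp > 0) {
            sd_ms <- 1000 * 1.875 * amp / saccade_peak_velocity(amp)
            j1 <- i0 - 1
            j0 <- max(1, j1 - round(sd_ms * hz / 1000) + 1)
            if (j1 >= j0) {
              tau <- seq(0, 1, length.out = j1 - j0 + 1)
              pos_x[j0:j1] <- px + (plan$x[i] - px) * minjerk(tau)
              pos_y[j0:j1] <- py + (plan$y[i] - py) * minjerk(tau)
            }
          }
        }
      }
    }
    x <- pos_x + stats::rnorm(n, sd = profile$noise_sd)
    y <- pos_y + stats::rnorm(n, sd = profile$noise_sd)
    valid <- rep(TRUE, n)
    # blinks: invalid run flanked by 20 ms high-velocity artifacts
    n_blinks <- stats::rpois(1, profile$blink_rate * dur / 1000)
    if (n_blinks > 0) {
      for (b in seq_len(n_blinks)) {
        b0 <- sample.int(max(1, n - profile$blink_ms), 1)
        b1 <- min(n, b0 + profile$blink_ms - 1)
        valid[b0:b1] <- FALSE
        art <- 20
        a0 <- max(1, b0 - art); a1 <- min(n, b1 + art)
        if (a0 < b0) y[a0:(b0 - 1)] <- y[a0:(b0 - 1)] +
            seq(0, -3, length.out = b0 - a0)
        if (a1 > b1) y[(b1 + 1):a1] <- y[(b1 + 1):a1] +
            seq(-3, 0, length.out = a1 - b1)
      }
    }
    if (profile$dropout_rate > 0) {
      valid[stats::runif(n) < profile$dropout_rate] <- FALSE
    }
    all_samples[[name]] <- data.frame(
      t_ms = onsets[[name]] + tt, x_deg = x, y_deg = y,
      valid = valid, interval = name
    )
    if (!is.null(plan) && nrow(plan)) {
      truth[[name]] <- data.frame(interval = name,
                                  onset = onsets[[name]] + plan$onset,
                                  offset = onsets[[name]] + plan$onset + plan$duration,
                                  x = plan$x, y = plan$y,
                                  duration = plan$duration)
    }
  }
  structure(list(
    samples = do.call(rbind, c(all_samples, list(make.row.names = FALSE))),
    intervals = data.frame(interval = names(durs),
                           onset = unname(onsets),
                           offset = unname(onsets + durs)),
    truth = if (length(truth)) do.call(rbind, c(truth, list(make.row.names = FALSE)))
            else NULL,
    hz = hz
  ), class = "gaze_stream")
}

#' Write / read a gaze stream as CSV
#'
#' @param stream A `gaze_stream`.
#' @param path File path.
#' @return `path` (write) or a samples data frame (read), invisibly for write.
#' @export
write_gaze_csv <- function(stream, path) {
  utils::write.csv(stream$samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path) {
  utils::read.csv(path)
}
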