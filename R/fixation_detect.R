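# Adaptive velocity-based fixation detection, per stimulus interval:
# Savitzky-Golay smoothing and differentiation of the position signal, a
# data-driven saccade peak-velocity threshold iterated from an initial 80
# deg/s (mean + 6 SD of sub-threshold samples), saccade onset/offset
# refinement to a lower adaptive threshold, blink/noise labeling (invalid
# runs and physiologically impossible velocities), and a 100 ms minimum
# fixation duration.

#' Detector parameters
#'
#' @param init_peak_vt Initial saccade peak-velocity threshold (deg/s).
#' @param min_fix_ms Minimum fixation duration (ms).
#' @param smooth_ms Savitzky-Golay window (ms; odd number of samples used).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param onset_sds Onset/offset threshold: mean + `onset_sds` * SD of
#'   sub-threshold velocity.
#' @param peak_sds Adaptive peak threshold: mean + `peak_sds` * SD.
#' @param blink_vt Velocity above which samples are labeled noise (deg/s).
#' @param min_adapt_ms Minimum valid data required to adapt the threshold;
#'   below this the initial threshold is used as-is.
#' @param min_peak_vt,min_onset_vt Floors on the adapted thresholds (deg/s);
#'   keep the detector sane on noise-free signals where the sub-threshold
#'   velocity SD collapses to zero.
#' @return List of class `detector_params`.
#' @export
detector_params <- function(init_peak_vt = 80, min_fix_ms = 100,
                            smooth_ms = 20, sg_order = 2,
                            onset_sds = 3, peak_sds = 6,
                            blink_vt = 1000, min_adapt_ms = 200,
                            min_peak_vt = 10, min_onset_vt = 5) {
  structure(as.list(environment()), class = "detector_params")
}

#' Detect fixations in a gaze stream
#'
#' Runs the adaptive velocity-based event detector independently on each
#' stimulus interval and returns the detected fixations with per-interval
#' sample labels.
#'
#' @param stream A `gaze_stream` (or a list with `samples`, `intervals`,
#'   `hz`).
#' @param params A [detector_params()].
#' @return List with `fixations` (data frame: `interval`, `onset`, `offset`,
#'   `duration`, `x`, `y`, `n_samples`) and `labels` (per interval: fractions
#'   of missing and blink/noise samples).
#' @export
detect_fixations <- function(stream, params = detector_params()) {
  hz <- if (!is.null(stream$hz)) stream$hz else 1000
  fix_all <- list()
  lab_all <- list()
  for (iv in stream$intervals$interval) {
    sub <- stream$samples[stream$samples$interval == iv, ]
    res <- detect_interval(sub, hz, params)
    if (!is.null(res$fixations) && nrow(res$fixations)) {
      res$fixations$interval <- iv
      fix_all[[iv]] <- res$fixations
    }
    lab_all[[iv]] <- data.frame(interval = iv,
                                frac_missing = res$frac_missing,
                                frac_blink_noise = res$frac_blink_noise,
                                n_samples = nrow(sub))
  }
  fixations <- if (length(fix_all)) {
    out <- do.call(rbind, c(fix_all, list(make.row.names = FALSE)))
    out[, c("interval", "onset", "offset", "duration", "x", "y", "n_samples")]
  } else {
    data.frame(interval = character(), onset = numeric(), offset = numeric(),
               duration = numeric(), x = numeric(), y = numeric(),
               n_samples = integer())
  }
  list(fixations = fixations,
       labels = do.call(rbind, c(lab_all, list(make.row.names = FALSE))))
}

detect_interval <- function(sub, hz, params) {
  n <- nrow(sub)
  empty <- list(fixations = NULL, frac_missing = 1, frac_blink_noise = 1)
  if (n < 3) return(empty)
  valid <- sub$valid
  frac_missing <- mean(!valid)
  # interpolate through invalid samples so filtering stays contiguous
  x <- sub$x_deg; y <- sub$y_deg
  if (any(!valid) && any(valid)) {
    idx <- seq_len(n)
    x[!valid] <- stats::approx(idx[valid], x[valid], xout = idx[!valid],
                               rule = 2)$y
    y[!valid] <- stats::approx(idx[valid], y[valid], xout = idx[!valid],
                               rule = 2)$y
  }
  if (all(!valid)) return(empty)

  win <- max(5, round(params$smooth_ms * hz / 1000))
  if (win %% 2 == 0) win <- win + 1
  if (win >= n) win <- if (n %% 2 == 0) n - 1 else n - 2
  if (win < params$sg_order + 2) return(empty)
  vx <- signal::sgolayfilt(x, p = params$sg_order, n = win, m = 1) * hz
  vy <- signal::sgolayfilt(y, p = params$sg_order, n = win, m = 1) * hz
  vel <- sqrt(vx^2 + vy^2)

  # physiologically impossible movement is judged on the raw sample-to-sample
  # velocity (smoothing would average single-sample artifacts away)
  raw_vel <- c(0, sqrt(diff(sub$x_deg)^2 + diff(sub$y_deg)^2) * hz)
  blink_noise <- !valid | raw_vel > params$blink_vt | vel > params$blink_vt
  frac_blink_noise <- mean(blink_noise)

  # adaptive peak-velocity threshold (mean + k SD of sub-threshold velocity)
  pt <- params$init_peak_vt
  usable <- !blink_noise
  if (sum(usable) >= params$min_adapt_ms * hz / 1000) {
    for (it in 1:50) {
      s <- vel[usable & vel < pt]
      if (length(s) < 2) break
      new_pt <- max(params$min_peak_vt,
                    mean(s) + params$peak_sds * stats::sd(s))
      if (!is.finite(new_pt) || abs(new_pt - pt) < 1) { pt <- new_pt; break }
      pt <- new_pt
    }
    if (!is.finite(pt)) pt <- params$init_peak_vt
    pt <- max(pt, params$min_peak_vt)
    s <- vel[usable & vel < pt]
    onset_t <- if (length(s) >= 2) mean(s) + params$onset_sds * stats::sd(s)
               else pt / 2
  } else {
    onset_t <- pt / 2
  }
  onset_t <- max(onset_t, params$min_onset_vt)

  # saccade samples: above-peak-threshold runs extended down to the
  # onset/offset threshold
  event <- blink_noise
  above <- which(vel >= pt & !blink_noise)
  if (length(above)) {
    runs <- split(above, cumsum(c(1, diff(above) != 1)))
    for (r in runs) {
      i0 <- r[1]
      while (i0 > 1 && vel[i0 - 1] > onset_t && !blink_noise[i0 - 1]) i0 <- i0 - 1
      i1 <- r[length(r)]
      while (i1 < n && vel[i1 + 1] > onset_t && !blink_noise[i1 + 1]) i1 <- i1 + 1
      event[i0:i1] <- TRUE
    }
  }

  # fixations: non-event gaps of at least min_fix_ms
  free <- which(!event)
  fixations <- NULL
  if (length(free)) {
    runs <- split(free, cumsum(c(1, diff(free) != 1)))
    min_n <- params$min_fix_ms * hz / 1000
    rows <- lapply(runs, function(r) {
      rv <- r[valid[r]]
      if (length(r) < min_n || length(rv) < 2) return(NULL)
      data.frame(onset = sub$t_ms[r[1]], offset = sub$t_ms[r[length(r)]],
                 duration = (length(r)) * 1000 / hz,
                 x = mean(sub$x_deg[rv]), y = mean(sub$y_deg[rv]),
                 n_samples = length(r))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) fixations <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  list(fixations = fixations, frac_missing = frac_missing,
       frac_blink_noise = frac_blink_noise)
}

#' Per-trial eye-data quality control
#'
#' Excludes a trial when, in any stimulus interval, more than `max_missing`
#' of samples are missing or fall outside the display, more than `max_noise`
#' are labeled blink/noise by the detector, or no fixation was detected
#' within the display boundary.
#'
#' @param stream A `gaze_stream`.
#' @param detections Result of [detect_fixations()].
#' @param display_deg Display half-extent is `display_deg / 2` per axis:
#'   `c(width, height)` in degrees.
#' @param max_missing,max_noise Exclusion fractions.
#' @return List of class `trial_gaze_qc`: `keep` (logical), `reason`
#'   (character or `NA`), and the per-interval `table`.
#' @export
qc_trial <- function(stream, detections, display_deg = c(24, 20),
                     max_missing = 0.05, max_noise = 0.20) {
  hw <- display_deg[1] / 2; hh <- display_deg[2] / 2
  tabs <- list()
  for (iv in stream$intervals$interval) {
    sub <- stream$samples[stream$samples$interval == iv, ]
    outside <- abs(sub$x_deg) > hw | abs(sub$y_deg) > hh
    frac_missing <- mean(!sub$valid | outside)
    lab <- detections$labels[detections$labels$interval == iv, ]
    fx <- detections$fixations[detections$fixations$interval == iv, ]
    fix_in_display <- nrow(fx) > 0 && any(abs(fx$x) <= hw & abs(fx$y) <= hh)
    tabs[[iv]] <- data.frame(interval = iv, frac_missing = frac_missing,
                             frac_blink_noise = lab$frac_blink_noise,
                             fixation_found = fix_in_display)
  }
  tab <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  reason <- NA_character_
  if (any(tab$frac_missing > max_missing)) {
    reason <- "missing-data"
  } else if (any(tab$frac_blink_noise > max_noise)) {
    reason <- "noise"
  } else if (any(!tab$fixation_found)) {
    reason <- "no-fixation"
  }
  structure(list(keep = is.na(reason), reason = reason, table = tab),
            class = "trial_gaze_qc")
}

#' Filter detected fixations
#'
#' Drops fixations outside the display bounds, then sequentially drops any
#' fixation whose centroid lies within `min_sep_deg` of the previous retained
#' fixation's centroid (within interval, in time order).
#'
#' @param fixations Fixation data frame (as from [detect_fixations()]).
#' @param display_deg Display extent `c(width, height)` in degrees.
#' @param min_sep_deg Minimum separation from the previous retained fixation.
#' @return Filtered fixation data frame.
#' @export
filter_fixations <- function(fixations, display_deg = c(24, 20),
                             min_sep_deg = 1) {
  if (!nrow(fixations)) return(fixations)
  hw <- display_deg[1] / 2; hh <- display_deg[2] / 2
  fixations <- fixations[abs(fixations$x) <= hw & abs(fixations$y) <= hh, ,
                         drop = FALSE]
  keep <- logical(nrow(fixations))
  for (iv in unique(fixations$interval)) {
    idx <- which(fixations$interval == iv)
    idx <- idx[order(fixations$onset[idx])]
    last <- NULL
    for (i in idx) {
      if (is.null(last) ||
          sqrt((fixations$x[i] - fixations$x[last])^2 +
               (fixations$y[i] - fixations$y[last])^2) >= min_sep_deg) {
        keep[i] <- TRUE
        last <- i
      }
    }
  }
  fixations[keep, , drop = FALSE]
}

#' Attribute fixations to tiles and reflectances
#'
#' Maps each within-image fixation to the containing tile of the interval's
#' scene and that tile's assigned reflectance; fixations inside the display
#' but outside the tiled image are flagged untiled (`NA` tile/reflectance).
#'
#' @param fixations Fixation data frame with an `interval` column
#'   (`"target"`, `"comp1"`, `"comp2"`).
#' @param scenes List of three [scene_spec()]s in interval order.
#' @param grid Tile grid.
#' @param refl_names Reflectance names indexing assignments.
#' @return `fixations` with `tile` and `reflectance` columns added.
#' @export
attribute_fixations <- function(fixations, scenes, grid, refl_names) {
  stopifnot(length(scenes) == 3)
  fixations$tile <- NA_integer_
  fixations$reflectance <- NA_character_
  if (!nrow(fixations)) return(fixations)
  for (i in seq_len(3)) {
    iv <- c("target", "comp1", "comp2")[i]
    idx <- which(fixations$interval == iv)
    if (!length(idx)) next
    tiles <- locate_tile(grid, fixations$x[idx], fixations$y[idx])
    fixations$tile[idx] <- tiles
    hit <- !is.na(tiles)
    fixations$reflectance[idx[hit]] <-
      refl_names[scenes[[i]]$assignment[tiles[hit]]]
  }
  fixations
}
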