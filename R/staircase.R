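# The trial/session engine: 1-up-2-down staircases over the nominal step
# range 1..50 with the step-size schedule 15 -> 10/5/3/1 after reversals
# 1..4, termination at the 8th reversal or 50 trials, twelve interleaved
# staircases per session (three per chromatic direction) preceded by a
# 12-trial training block.

.staircase_steps <- c(15, 10, 5, 3, 1)

#' Session timing and design configuration
#'
#' @param profile `"exp1"` (stereo apparatus: target 2100 ms, comparison
#'   600 ms, blank 420 ms) or `"exp2"` (eye-tracking apparatus: 2370 / 870 /
#'   750 ms).
#' @param n_target_versions Size of the target-scene pool drawn from on each
#'   trial.
#' @param directions Chromatic directions run in the session.
#' @return List of class `session_config`.
#' @export
session_config <- function(profile = c("exp1", "exp2"),
                           n_target_versions = 30,
                           directions = c("blue", "yellow", "red", "green")) {
  profile <- match.arg(profile)
  intervals <- switch(profile,
    exp1 = c(target = 2100, comparison = 600, blank = 420),
    exp2 = c(target = 2370, comparison = 870, blank = 750)
  )
  structure(list(profile = profile, intervals_ms = intervals,
                 n_target_versions = n_target_versions,
                 directions = directions),
            class = "session_config")
}

#' Create a staircase
#'
#' @param direction Chromatic direction the staircase controls.
#' @param start_level Starting nominal level (1..50).
#' @param training Training staircases keep a fixed 10-unit step and are
#'   excluded from analysis.
#' @return A `staircase` state object.
#' @export
staircase_new <- function(direction, start_level, training = FALSE) {
  stopifnot(start_level >= 1, start_level <= 50)
  structure(list(
    direction = direction,
    level = as.integer(start_level),
    start_level = as.integer(start_level),
    step_idx = 1L,
    reversals = 0L,
    consec_correct = 0L,
    trials = 0L,
    last_move = 0L,
    levels = integer(50),
    corrects = logical(50),
    training = training,
    finished = FALSE
  ), class = "staircase")
}

staircase_step_size <- function(s) {
  if (s$training) 10 else .staircase_steps[s$step_idx]
}

#' Advance a staircase by one trial
#'
#' 1-up-2-down: two consecutive correct responses move the level down by the
#' current step (and reset the counter); any incorrect response moves it up.
#' A move whose direction differs from the previous move's direction counts
#' as a reversal (the first move establishes direction without counting);
#' step-size reductions triggered by reversals 1..4 take effect from the next
#' move. Levels clamp to `[1, 50]`; clamping alone is not a reversal. The
#' staircase finishes at the 8th reversal or the 50th trial.
#'
#' @param s A `staircase` state.
#' @param correct Logical response for the trial run at `s$level`.
#' @return The updated `staircase` state.
#' @export
update_staircase <- function(s, correct) {
  if (s$finished) stop("state error: update on finished staircase", call. = FALSE)
  s$trials <- s$trials + 1L
  s$levels[s$trials] <- s$level
  s$corrects[s$trials] <- correct
  move <- 0L
  if (correct) {
    s$consec_correct <- s$consec_correct + 1L
    if (s$consec_correct >= 2L) {
      move <- -1L
      s$consec_correct <- 0L
    }
  } else {
    move <- 1L
    s$consec_correct <- 0L
  }
  if (move != 0L) {
    reversal <- s$last_move != 0L && move != s$last_move
    step <- staircase_step_size(s) # step in force for this move
    s$level <- max(1L, min(50L, s$level + move * as.integer(step)))
    s$last_move <- move
    if (reversal) {
      s$reversals <- s$reversals + 1L
      s$step_idx <- min(s$reversals + 1L, 5L) # effective from the next move
    }
  }
  if (s$reversals >= 8L || s$trials >= 50L) s$finished <- TRUE
  s
}

#' Run one experimental session
#'
#' Executes the 12-trial training block (one 3-trial training staircase per
#' direction, start level drawn from 31--40, fixed 10-unit step, flagged and
#' excluded from analysis) followed by the 12 interleaved experimental
#' staircases (per direction: one start level drawn from each of 11--20,
#' 21--30, 31--40), with the staircase for each trial chosen at random from
#' those not yet finished. Each trial randomizes the comparison-interval
#' order, draws two distinct target-scene versions from the pool, and queries
#' the observer at the direction's actual Delta E for the staircase's level.
#'
#' @param observer A `sim_observer`.
#' @param condition `"fixed"` or `"shuffled"`.
#' @param series An `illuminant_series` (source of actual Delta E values).
#' @param config A [session_config()].
#' @param seed Integer seed for the session.
#' @param observer_id,session Identifiers recorded in the log.
#' @return A `session_log`: list with `trials` (data frame, one row per
#'   trial), `staircases` (final states), `observer_id`, `condition`,
#'   `session`, `config`.
#' @export
run_session <- function(observer, condition, series, config = session_config(),
                        seed = 1, observer_id = "sim", session = 1L) {
  lookup <- series_lookup_matrix(series, config$directions)
  with_seed(seed, {
    run_session_impl(observer, condition, lookup, config, observer_id, session)
  })
}

# actual Delta E as a directions x 50 matrix for O(1) trial lookup
series_lookup_matrix <- function(series, directions) {
  lk <- series$lookup
  m <- matrix(NA_real_, nrow = length(directions), ncol = series$n_steps,
              dimnames = list(directions, NULL))
  for (d in directions) {
    rows <- lk[lk$direction == d, ]
    m[d, rows$nominal_step] <- rows$actual_delta_e
  }
  if (anyNA(m)) stop("series does not cover all requested directions/steps",
                     call. = FALSE)
  m
}

run_session_impl <- function(observer, condition, lookup, config,
                             observer_id, session) {
  directions <- rownames(lookup)
  random_obs <- inherits(observer, "random_responder")

  stairs <- list()
  for (d in directions) {
    stairs[[paste0("train_", d)]] <- staircase_new(d, sample(31:40, 1),
                                                   training = TRUE)
  }
  band <- list(11:20, 21:30, 31:40)
  for (d in directions) {
    for (b in 1:3) {
      stairs[[paste0(d, "_", b)]] <- staircase_new(d, sample(band[[b]], 1))
    }
  }
  ids <- names(stairs)
  training <- vapply(stairs, function(s) s$training, logical(1))

  n_max <- 12L * 50L + 12L
  trial_idx <- integer(n_max); sc_id <- character(n_max)
  dir_v <- character(n_max); level_v <- integer(n_max); de_v <- numeric(n_max)
  tfirst <- logical(n_max); scn1 <- integer(n_max); scn2 <- integer(n_max)
  corr <- logical(n_max); train_v <- logical(n_max)

  t <- 0L
  run_trial <- function(key) {
    s <- stairs[[key]]
    t <<- t + 1L
    de <- lookup[s$direction, s$level]
    scenes <- sample.int(config$n_target_versions, 2L)
    correct <- if (random_obs) stats::runif(1) < 0.5 else
      respond(observer, de, condition, s$direction)
    trial_idx[t] <<- t; sc_id[t] <<- key
    dir_v[t] <<- s$direction; level_v[t] <<- s$level; de_v[t] <<- de
    tfirst[t] <<- stats::runif(1) < 0.5
    scn1[t] <<- scenes[1]; scn2[t] <<- scenes[2]
    corr[t] <<- correct; train_v[t] <<- s$training
    stairs[[key]] <<- update_staircase(s, correct)
  }

  # training block: 3 trials per direction's training staircase, interleaved
  train_ids <- ids[training]
  order_t <- resample(rep(train_ids, each = 3))
  for (key in order_t) run_trial(key)

  # experimental block
  main_ids <- ids[!training]
  repeat {
    active <- main_ids[!vapply(stairs[main_ids], `[[`, logical(1), "finished")]
    if (!length(active)) break
    run_trial(resample(active, 1))
  }

  keep <- seq_len(t)
  trials <- data.frame(
    trial = trial_idx[keep], staircase = sc_id[keep], direction = dir_v[keep],
    nominal_level = level_v[keep], actual_delta_e = de_v[keep],
    target_first = tfirst[keep], scene_target = scn1[keep],
    scene_comparison = scn2[keep], correct = corr[keep],
    is_training = train_v[keep]
  )
  structure(list(observer_id = observer_id, condition = condition,
                 session = session, trials = trials,
                 staircases = stairs, config = config),
            class = "session_log")
}

#' Reconstruct staircase trajectories from a session log
#'
#' Deterministically replays every staircase from its recorded trial sequence
#' and verifies that each recorded level matches the level the 1-up-2-down
#' rule prescribes; a mismatch raises a validation error naming the trial.
#'
#' @param log A `session_log`.
#' @return Named list of reconstructed final `staircase` states.
#' @export
replay_log <- function(log) {
  out <- list()
  for (key in unique(log$trials$staircase)) {
    rows <- log$trials[log$trials$staircase == key, ]
    s0 <- log$staircases[[key]]
    s <- staircase_new(rows$direction[1], rows$nominal_level[1],
                       training = isTRUE(s0$training))
    for (i in seq_len(nrow(rows))) {
      if (rows$nominal_level[i] != s$level) {
        stop(sprintf("replay validation error at trial %d (staircase %s): recorded level %d, rule prescribes %d",
                     rows$trial[i], key, rows$nominal_level[i], s$level),
             call. = FALSE)
      }
      s <- update_staircase(s, rows$correct[i])
    }
    out[[key]] <- s
  }
  out
}
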