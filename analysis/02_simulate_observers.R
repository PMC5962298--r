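#!/usr/bin/env Rscript
# Simulate a cohort of parametric observers through the full experiment:
# two sessions per condition of 12 interleaved 1-up-2-down staircases.
# Observers get a fixed-condition threshold drawn from the 6-15 dE band and
# a shuffled-condition threshold elevated by an observer-specific amount, so
# downstream analyses see the qualitative structure of real data (condition
# effect, across-observer variation) with known ground truth. Writes one
# tidy CSV of all trials.

suppressPackageStartupMessages(library(illumdisc))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
master_seed <- 20240101

series <- build_illuminant_series()
n_obs <- 10

set.seed(master_seed)
truth <- data.frame(
  observer = sprintf("obs%02d", seq_len(n_obs)),
  th_fixed = runif(n_obs, 6, 15),
  elevation = runif(n_obs, 8, 25)
)
truth$th_shuffled <- truth$th_fixed + truth$elevation
write.csv(truth, file.path(out_dir, "observer_truth.csv"), row.names = FALSE)

# per-condition alpha resolution uses "condition.direction" keys; register
# all four directions explicitly
observers <- setNames(lapply(seq_len(n_obs), function(i) {
  dirs <- c("blue", "yellow", "red", "green")
  alphas <- c(setNames(rep(alpha_for_threshold(truth$th_fixed[i]), 4),
                       paste("fixed", dirs, sep = ".")),
              setNames(rep(alpha_for_threshold(truth$th_shuffled[i]), 4),
                       paste("shuffled", dirs, sep = ".")))
  psychometric_observer(alpha = alphas, beta = 3, lapse = 0.01)
}), truth$observer)

cfg <- experiment_config(seed = master_seed, profile = "exp1",
                         n_observers = n_obs)
logs <- simulate_experiment(observers, series, cfg)

trials <- do.call(rbind, lapply(logs, function(log) {
  cbind(observer = log$observer_id, condition = log$condition,
        session = log$session, log$trials)
}))
write.csv(trials, file.path(out_dir, "session_trials.csv"), row.names = FALSE)
cat(sprintf("simulated %d observers x 2 conditions x 2 sessions: %d trials\n",
            n_obs, nrow(trials)))
cat("wrote", file.path(out_dir, "session_trials.csv"), "\n")
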