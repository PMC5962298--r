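make_stream <- function(profile, seed = 1, cfg = session_config("exp2")) {
  simulate_gaze(profile, cfg, seed = seed)
}

test_that("detector finds planted fixations and rejects sub-100 ms dwells", {
  # hand-built stream: two fixations separated by one saccade, plus an
  # 80 ms dwell that must not be reported
  hz <- 1000
  seg <- function(t0, n, x, y) {
    data.frame(t_ms = t0 + seq_len(n) - 1, x_deg = x, y_deg = y,
               valid = TRUE, interval = "target")
  }
  sacc <- function(t0, n, from, to) {
    tau <- seq(0, 1, length.out = n)
    mj <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
    data.frame(t_ms = t0 + seq_len(n) - 1,
               x_deg = from[1] + (to[1] - from[1]) * mj,
               y_deg = from[2] + (to[2] - from[2]) * mj,
               valid = TRUE, interval = "target")
  }
  samples <- rbind(
    seg(0, 400, -3, 0),
    sacc(400, 40, c(-3, 0), c(4, 2)),
    seg(440, 300, 4, 2),
    sacc(740, 40, c(4, 2), c(-1, -4)),
    seg(780, 80, -1, -4) # 80 ms: below the minimum fixation duration
  )
  set.seed(3)
  samples$x_deg <- samples$x_deg + rnorm(nrow(samples), sd = 0.03)
  samples$y_deg <- samples$y_deg + rnorm(nrow(samples), sd = 0.03)
  stream <- list(samples = samples,
                 intervals = data.frame(interval = "target", onset = 0,
                                        offset = 860),
                 hz = hz)
  det <- detect_fixations(stream)
  fx <- det$fixations
  expect_equal(nrow(fx), 2)
  expect_lt(abs(fx$x[1] - (-3)), 0.05)
  expect_lt(abs(fx$y[2] - 2), 0.05)
  expect_true(all(fx$duration >= 100))
})

test_that("a stationary noisy interval yields exactly one spanning fixation", {
  set.seed(6)
  n <- 870
  stream <- list(
    samples = data.frame(t_ms = seq_len(n) - 1,
                         x_deg = 1 + rnorm(n, sd = 0.05),
                         y_deg = -2 + rnorm(n, sd = 0.05),
                         valid = TRUE, interval = "comp1"),
    intervals = data.frame(interval = "comp1", onset = 0, offset = n),
    hz = 1000
  )
  det <- detect_fixations(stream)
  expect_equal(nrow(det$fixations), 1)
  expect_gt(det$fixations$duration, 0.9 * n)
})

test_that("detector recovers >= 95% of planted fixations under realistic noise", {
  cfg <- session_config("exp2")
  prof <- gaze_profile(mean_fix_ms = 300, blink_rate = 0.2,
                       dropout_rate = 0.001, noise_sd = 0.1)
  tot <- 0; rec <- 0
  for (seed in 1:25) {
    st <- simulate_gaze(prof, cfg, seed = seed)
    det <- detect_fixations(st)
    tru <- st$truth[st$truth$duration >= 150, ]
    for (i in seq_len(nrow(tru))) {
      d <- det$fixations[det$fixations$interval == tru$interval[i], ]
      tot <- tot + 1
      if (nrow(d) &&
          min(sqrt((d$x - tru$x[i])^2 + (d$y - tru$y[i])^2)) < 0.3) {
        rec <- rec + 1
      }
    }
  }
  expect_gte(rec / tot, 0.95)
})

test_that("QC rules fire on constructed violations", {
  cfg <- session_config("exp2")
  prof <- gaze_profile(blink_rate = 0, dropout_rate = 0, noise_sd = 0.05)
  st <- simulate_gaze(prof, cfg, seed = 5)
  det <- detect_fixations(st)
  clean <- qc_trial(st, det)
  expect_true(clean$keep)
  # 6% missing in comp1: excluded for missing data
  st2 <- st
  idx <- which(st2$samples$interval == "comp1")
  st2$samples$valid[idx[seq_len(ceiling(0.06 * length(idx)))]] <- FALSE
  qc2 <- qc_trial(st2, detect_fixations(st2))
  expect_false(qc2$keep)
  expect_equal(qc2$reason, "missing-data")
  # 25% high-velocity noise in the target interval: excluded for noise
  st3 <- st
  idx <- which(st3$samples$interval == "target")
  bad <- idx[seq_len(ceiling(0.25 * length(idx)))]
  st3$samples$x_deg[bad] <- st3$samples$x_deg[bad] +
    rep(c(0, 3), length.out = length(bad)) # 3 deg/ms jumps
  det3 <- detect_fixations(st3)
  qc3 <- qc_trial(st3, det3)
  expect_false(qc3$keep)
  expect_equal(qc3$reason, "noise")
  # gaze parked outside the display: no in-display fixation
  st4 <- st
  st4$samples$x_deg <- st4$samples$x_deg + 40
  qc4 <- qc_trial(st4, detect_fixations(st4))
  expect_false(qc4$keep)
  expect_equal(qc4$reason, "missing-data") # outside display counts as missing
})

test_that("fixation filter applies the sequential 1-degree rule", {
  fx <- data.frame(interval = "target",
                   onset = c(0, 200, 400), offset = c(150, 350, 550),
                   duration = 150, x = c(0, 0.9, 1.8), y = 0,
                   n_samples = 150)
  out <- filter_fixations(fx)
  expect_equal(out$x, c(0, 1.8)) # 0.9 dropped; 1.8 is >= 1 from 0
  fx2 <- fx; fx2$x <- c(0, 0.5, 3)
  expect_equal(filter_fixations(fx2)$x, c(0, 3))
  fx3 <- fx; fx3$x <- c(0, 2, 4)
  expect_equal(filter_fixations(fx3)$x, c(0, 2, 4)) # all kept
  # outside-display fixations are dropped first
  fx4 <- fx; fx4$x <- c(0, 30, 1.5)
  expect_equal(filter_fixations(fx4)$x, c(0, 1.5))
})

test_that("fixations map to the containing tile and its reflectance", {
  asg <- assign_reflectances(the_grid, seed = 2)
  scenes <- lapply(1:3, function(k) {
    scene_spec(paste0("s", k), "fixed", "target", assignment = asg)
  })
  i <- 40 # an interior tile
  fx <- data.frame(interval = c("target", "comp1"),
                   onset = c(0, 3200), offset = c(200, 3400), duration = 200,
                   x = c(the_grid$x[i], 100), y = c(the_grid$y[i], 0),
                   n_samples = 200)
  out <- attribute_fixations(fx, scenes, the_grid, names(the_refl))
  expect_equal(out$tile[1], the_grid$tile_id[i])
  expect_equal(out$reflectance[1], names(the_refl)[asg[i]])
  expect_true(is.na(out$tile[2])) # outside the image: untiled
  # shuffled condition: same position, different assignments per interval
  scenes2 <- lapply(1:3, function(k) {
    scene_spec(paste0("s", k), "shuffled", "target",
               assignment = assign_reflectances(the_grid, seed = k + 10))
  })
  fx2 <- data.frame(interval = c("target", "comp1", "comp2"),
                    onset = c(0, 3200, 4800), offset = c(200, 3400, 5000),
                    duration = 200, x = the_grid$x[i], y = the_grid$y[i],
                    n_samples = 200)
  out2 <- attribute_fixations(fx2, scenes2, the_grid, names(the_refl))
  expect_equal(out2$tile, rep(the_grid$tile_id[i], 3))
  asg_at <- vapply(scenes2, function(s) s$assignment[i], integer(1))
  expect_equal(out2$reflectance, names(the_refl)[asg_at])
})

test_that("fixation counts and joint spread match hand computations", {
  fx <- data.frame(trial = c(1, 1, 1, 2, 2, 2, 2, 2),
                   interval = c("target", "target", "comp1",
                                "target", "target", "comp1", "comp1", "comp2"),
                   x = c(1, -1, 0, 1, 1, 0, 2, 5),
                   y = c(0, 0, 1, 0, 0, 1, 1, 5),
                   reflectance = "red")
  fc <- fixation_counts(fx)
  expect_equal(fc$mean_count[fc$interval == "target"], 2)
  expect_equal(fc$se[fc$interval == "target"], 0)
  expect_equal(fc$mean_count[fc$interval == "comp1"], 1.5)
  expect_equal(fc$se[fc$interval == "comp1"], sd(c(1, 2)) / sqrt(2))
  # spread: target xs are (1,-1,1,1), ys 0 -> population sds
  xs <- c(1, -1, 1, 1)
  expect_equal(joint_spread(fx, "target"), sqrt(mean((xs - mean(xs))^2)))
  # fixations at (-1,0),(1,0) only: spread 1 under population convention
  fx2 <- data.frame(trial = 1, interval = "target", x = c(-1, 1), y = 0,
                    reflectance = NA)
  expect_equal(joint_spread(fx2, "target"), 1)
  expect_true(is.na(joint_spread(fx2, "comp1")))
  # isotropic cloud: spread ~ sd * sqrt(2)
  set.seed(9)
  fx3 <- data.frame(trial = 1, interval = "target",
                    x = rnorm(4000, sd = 1.5), y = rnorm(4000, sd = 1.5),
                    reflectance = NA)
  expect_equal(joint_spread(fx3, "target"), 1.5 * sqrt(2), tolerance = 0.05)
})

test_that("reflectance overlap matches definitional toy cases", {
  fx <- data.frame(trial = 1,
                   interval = c("target", "target", "comp1", "comp1"),
                   x = 0, y = 0,
                   reflectance = c("A", "C", "A", "B"))
  ro <- reflectance_overlap(fx)
  expect_equal(ro$overlap[ro$comparison == "comp1"], 0.5)
  # identical sets -> 1; disjoint -> 0
  fx$reflectance <- c("A", "B", "A", "B")
  expect_equal(reflectance_overlap(fx)$overlap[1], 1)
  fx$reflectance <- c("A", "B", "C", "D")
  expect_equal(reflectance_overlap(fx)$overlap[1], 0)
})

test_that("location overlap saturates with radius and respects boundaries", {
  fx <- data.frame(trial = 1,
                   interval = c("target", "comp1", "comp1"),
                   x = c(0, 0.5, 8), y = 0, reflectance = NA)
  expect_equal(location_overlap(fx, radius_deg = 1.5)$overlap[1], 0.5)
  expect_equal(location_overlap(fx, radius_deg = 100)$overlap[1], 1)
  fx2 <- data.frame(trial = 1, interval = c("target", "comp1"),
                    x = c(0, 5), y = 0, reflectance = NA)
  expect_equal(location_overlap(fx2, radius_deg = 1)$overlap[1], 0)
})

test_that("trial-shuffled null leaves permutation-invariant input unchanged", {
  # identical fixation sets on every trial: any pairing gives the same value
  fx <- do.call(rbind, lapply(1:6, function(tr) {
    data.frame(trial = tr,
               interval = c("target", "target", "comp1", "comp2"),
               x = c(0, 1, 0, 1), y = 0,
               reflectance = c("A", "B", "A", "B"))
  }))
  obs <- reflectance_overlap(fx)
  nul <- shuffled_null(fx, reflectance_overlap, seed = 2)
  expect_equal(nul$overlap, obs$overlap)
  expect_error(shuffled_null(fx[fx$trial == 1, ]), ">= 2 kept trials")
})

test_that("forced location reuse in the fixed condition yields unit overlap", {
  cfg <- experiment_config(profile = "exp2")
  cfg$gaze <- gaze_profile(mean_fix_ms = 500, location_reuse = 1,
                           reflectance_tracking = 0, noise_sd = 0,
                           blink_rate = 0, dropout_rate = 0)
  res <- simulate_fixation_trials(8, "fixed", the_refl, the_grid, cfg,
                                  seed = 2)
  expect_equal(reflectance_overlap(res$fixations)$overlap, c(1, 1))
  expect_equal(location_overlap(res$fixations)$overlap, c(1, 1))
  # and the shuffled null falls below the observed overlap
  nul <- shuffled_null(res$fixations, reflectance_overlap, seed = 3)
  expect_lt(mean(nul$overlap), 1)
})

test_that("per-reflectance distribution normalizes over attributed fixations", {
  fx <- data.frame(trial = 1, interval = "target", x = 0, y = 0,
                   reflectance = c("red", "red", "blue", NA))
  d <- per_reflectance_distribution(fx, c("red", "blue", "green"))
  tgt <- d[d$interval == "target", ]
  expect_equal(tgt$proportion[tgt$reflectance == "red"], 2 / 3)
  expect_equal(sum(tgt$proportion), 1)
  expect_equal(attr(d, "n_untiled"), 1)
})

test_that("Spearman correlation matches the rank formula with exact small-n p", {
  x <- 1:8
  y <- -x
  r <- correlate_with_thresholds(x, y)
  expect_equal(r$rho, -1)
  expect_lt(r$p, 0.001)
  # one swap in a monotone sequence: rho from the rank formula
  y2 <- c(1, 2, 3, 5, 4, 6, 7, 8)
  r2 <- correlate_with_thresholds(x, y2)
  d2 <- sum((rank(x) - rank(y2))^2)
  expect_equal(r2$rho, 1 - 6 * d2 / (8 * (8^2 - 1)))
  expect_equal(r2$method, "exact permutation")
  # exact p agrees with the classical algorithm
  ct <- suppressWarnings(cor.test(x, y2, method = "spearman", exact = TRUE))
  expect_equal(r2$p, ct$p.value, tolerance = 1e-9)
  # ties-only input flagged undefined
  r3 <- correlate_with_thresholds(rep(1, 6), 1:6)
  expect_true(is.na(r3$rho))
  expect_error(correlate_with_thresholds(1:3, 3:1), "at least 4")
})

test_that("gaze CSV round-trips", {
  prof <- gaze_profile()
  st <- simulate_gaze(prof, session_config("exp2"), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze_csv(st, path)
  df <- read_gaze_csv(path)
  expect_equal(nrow(df), nrow(st$samples))
  expect_equal(df$x_deg, st$samples$x_deg)
})
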