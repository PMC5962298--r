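# Threshold extraction: trials pooled across a direction's three staircases
# are ordered by actual Delta E and grouped into 10-trial bins (remainder
# merged into the last bin); a cumulative Weibull with fixed 0.5 guess rate
# and box-bounded lapse is fitted by maximum likelihood on the binned
# binomial counts; the threshold is the stimulus value at 70.71% correct
# (the 1-up-2-down equilibrium point). Sessions aggregate by averaging, with
# out-of-range session thresholds substituted by the direction's maximal
# actual test Delta E.

#' Bin trials by stimulus magnitude
#'
#' Stable sort by Delta E, consecutive groups of `bin_size`, remainder merged
#' into the final bin (which therefore holds `bin_size` to `2*bin_size - 1`
#' trials).
#'
#' @param delta_e Actual Delta E per trial.
#' @param correct Logical response per trial.
#' @param bin_size Trials per bin.
#' @return Data frame with `mean_delta_e`, `n`, `k` (number correct),
#'   `prop_correct`, ordered by `mean_delta_e`.
#' @export
bin_trials <- function(delta_e, correct, bin_size = 10) {
  n <- length(delta_e)
  stopifnot(length(correct) == n)
  if (n < bin_size) {
    stop(sprintf("insufficient data: %d trials for bin size %d", n, bin_size),
         call. = FALSE)
  }
  ord <- order(delta_e) # stable in R
  de <- delta_e[ord]; co <- correct[ord]
  n_bins <- n %/% bin_size
  sizes <- rep(bin_size, n_bins)
  sizes[n_bins] <- sizes[n_bins] + n %% bin_size
  idx <- rep(seq_len(n_bins), times = sizes)
  data.frame(
    mean_delta_e = as.numeric(tapply(de, idx, mean)),
    n = as.integer(sizes),
    k = as.integer(tapply(co, idx, sum)),
    prop_correct = as.numeric(tapply(co, idx, mean))
  )
}

# negative log-likelihood and gradient in theta = (log alpha, log beta, lapse)
.weibull_nll <- function(theta, x, n, k) {
  alpha <- exp(theta[1]); beta <- exp(theta[2]); lapse <- theta[3]
  z <- (x / alpha)^beta
  e <- exp(-z)
  p <- 0.5 + (0.5 - lapse) * (1 - e)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

.weibull_nll_grad <- function(theta, x, n, k) {
  alpha <- exp(theta[1]); beta <- exp(theta[2]); lapse <- theta[3]
  z <- (x / alpha)^beta
  e <- exp(-z)
  p <- 0.5 + (0.5 - lapse) * (1 - e)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  dldp <- -(k / p - (n - k) / (1 - p))
  dpdz <- (0.5 - lapse) * e
  lz <- log(pmax(z, 1e-300))
  c(sum(dldp * dpdz * (-beta * z)),  # d / d log alpha
    sum(dldp * dpdz * (z * lz)),     # d / d log beta
    sum(dldp * (-(1 - e))))          # d / d lapse
}

#' Maximum-likelihood cumulative-Weibull fit to binned data
#'
#' Maximizes the bin-level binomial log-likelihood of `p(x) = 0.5 + (0.5 -
#' lambda) (1 - exp(-(x/alpha)^beta))` over `(alpha, beta, lambda)` with the
#' guess rate fixed at 0.5 and the lapse box-bounded in `[0, 0.05]`.
#' Multistart over a small alpha x beta grid guards against local optima.
#'
#' @param binned Data frame from [bin_trials()] (needs >= 2 bins).
#' @param alpha_grid,beta_grid Multistart values.
#' @param alpha_max Upper box bound on alpha; fits driven to the bound
#'   describe performance flat at chance and yield out-of-range thresholds.
#' @return Object of class `weibull_fit`: list with `alpha`, `beta`, `lapse`,
#'   `guess`, `logLik`, `converged`.
#' @export
fit_weibull <- function(binned, alpha_grid = c(5, 15, 30, 60),
                        beta_grid = c(0.5, 2, 4), alpha_max = 1e4) {
  if (nrow(binned) < 2) stop("need at least 2 bins to fit", call. = FALSE)
  x <- binned$mean_delta_e
  if (diff(range(x)) < sqrt(.Machine$double.eps)) {
    stop("degenerate design: all bins at the same stimulus level", call. = FALSE)
  }
  n <- binned$n; k <- binned$k
  lower <- c(log(0.1), log(0.05), 0)
  upper <- c(log(alpha_max), log(50), 0.05)
  best <- NULL
  for (a0 in alpha_grid) {
    for (b0 in beta_grid) {
      fit <- tryCatch(
        stats::optim(c(log(a0), log(b0), 0.01), .weibull_nll,
                     gr = .weibull_nll_grad, x = x, n = n, k = k,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(factr = 1e7, maxit = 200)),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$value < best$value - 1e-9)) {
        best <- fit
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(alpha = NA_real_, beta = NA_real_, lapse = NA_real_,
                          guess = 0.5, logLik = NA_real_, converged = FALSE),
                     class = "weibull_fit"))
  }
  structure(list(alpha = exp(best$par[1]), beta = exp(best$par[2]),
                 lapse = best$par[3], guess = 0.5, logLik = -best$value,
                 converged = best$convergence == 0),
            class = "weibull_fit")
}

#' Threshold at a performance criterion
#'
#' Analytic inversion of the fitted function: `x = alpha * (-log(1 -
#' (criterion - guess) / (0.5 - lambda)))^(1/beta)`.
#'
#' @param fit A `weibull_fit`.
#' @param criterion Criterion probability (default 0.7071, the 1-up-2-down
#'   equilibrium).
#' @return Threshold in actual Delta E; `Inf` if the fit did not converge or
#'   the criterion is at/above the fitted asymptote (out of range rather than
#'   an error).
#' @export
threshold_from_fit <- function(fit, criterion = 0.7071) {
  if (!isTRUE(fit$converged) || !is.finite(fit$alpha)) return(Inf)
  q <- (criterion - fit$guess) / (0.5 - fit$lapse)
  if (q <= 0) stop("criterion must exceed the guess rate", call. = FALSE)
  if (q >= 1) return(Inf)
  fit$alpha * (-log(1 - q))^(1 / fit$beta)
}

#' Per-direction threshold estimates for one session
#'
#' Pools a session's non-training trials per direction across its three
#' staircases, bins, fits, and inverts at the criterion. A threshold is in
#' range when it does not exceed the direction's maximal actual test Delta E
#' (the actual value at nominal step 50); non-converged fits count as out of
#' range.
#'
#' @param log A `session_log` from [run_session()].
#' @param series The `illuminant_series` used in the session.
#' @param criterion Performance criterion.
#' @param bin_size Trials per bin.
#' @return Data frame: `observer`, `condition`, `session`, `direction`,
#'   `threshold`, `in_range`, plus fitted `alpha`, `beta`, `lapse`,
#'   `converged`.
#' @export
session_thresholds <- function(log, series, criterion = 0.7071, bin_size = 10) {
  tr <- log$trials[!log$trials$is_training, ]
  out <- lapply(unique(tr$direction), function(d) {
    sub <- tr[tr$direction == d, ]
    binned <- bin_trials(sub$actual_delta_e, sub$correct, bin_size)
    fit <- fit_weibull(binned)
    th <- threshold_from_fit(fit, criterion)
    data.frame(observer = log$observer_id, condition = log$condition,
               session = log$session, direction = d, threshold = th,
               in_range = is.finite(th) && th <= max_test_delta_e(series, d),
               alpha = fit$alpha, beta = fit$beta, lapse = fit$lapse,
               converged = fit$converged)
  })
  do.call(rbind, out)
}

#' Aggregate two session thresholds for one direction
#'
#' Out-of-range session thresholds are substituted by the direction's maximal
#' actual test Delta E (a lower bound on the session's true threshold), then
#' the two sessions are averaged. If both sessions are out of range the
#' result is the sentinel `NA` with `both_out_of_range = TRUE` (consumed by
#' the exclusion rules).
#'
#' @param th1,th2 Session thresholds (Delta E; may be `Inf`).
#' @param in_range1,in_range2 In-range flags for the two sessions.
#' @param max_de The direction's maximal actual test Delta E.
#' @return List with `threshold`, `substituted` (logical), and
#'   `both_out_of_range`.
#' @export
aggregate_sessions <- function(th1, th2, in_range1, in_range2, max_de) {
  if (!in_range1 && !in_range2) {
    return(list(threshold = NA_real_, substituted = FALSE,
                both_out_of_range = TRUE))
  }
  v1 <- if (in_range1) th1 else max_de
  v2 <- if (in_range2) th2 else max_de
  list(threshold = (v1 + v2) / 2, substituted = !(in_range1 && in_range2),
       both_out_of_range = FALSE)
}

#' Apply the preregistered observer exclusion rules
#'
#' Given an observer's full session-threshold table (2 conditions x 2
#' sessions x 4 directions), returns
#' * `"exclude_replace"` if any fixed-condition session threshold is out of
#'   range, or any session threshold in any condition falls below 1 Delta E;
#' * `"exclude_only"` if, in the shuffled condition, any direction is out of
#'   range in both sessions;
#' * `"keep"` otherwise.
#'
#' @param est Data frame as returned by [session_thresholds()] (rows for all
#'   conditions/sessions/directions of one observer).
#' @return Character decision.
#' @export
apply_exclusions <- function(est) {
  needed <- expand.grid(condition = unique(est$condition),
                        session = unique(est$session),
                        direction = unique(est$direction))
  have <- paste(est$condition, est$session, est$direction)
  miss <- setdiff(paste(needed$condition, needed$session, needed$direction), have)
  if (length(miss)) {
    stop(sprintf("incomplete estimate table; missing: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  fixed <- est[est$condition == "fixed", ]
  if (nrow(fixed) && any(!fixed$in_range)) return("exclude_replace")
  if (any(est$in_range & est$threshold < 1)) return("exclude_replace")
  shuffled <- est[est$condition == "shuffled", ]
  if (nrow(shuffled)) {
    for (d in unique(shuffled$direction)) {
      sub <- shuffled[shuffled$direction == d, ]
      if (nrow(sub) >= 2 && all(!sub$in_range)) return("exclude_only")
    }
  }
  "keep"
}

#' Random-responder exclusion null
#'
#' Simulates observers who respond at chance on every trial, runs each
#' through two full sessions of the 12-staircase protocol, extracts
#' per-session per-direction thresholds, and counts observers with at least
#' one direction out of range in both sessions — the criterion that excludes
#' an observer from the shuffled-surfaces analysis.
#'
#' @param n_observers Number of simulated observers.
#' @param series An `illuminant_series`.
#' @param config A [session_config()].
#' @param seed Integer seed.
#' @param sessions Sessions per observer.
#' @param progress_every Print progress every so many observers (0 = quiet).
#' @return List with `fraction_excluded`, `n_excluded`, `n_observers`, and
#'   `detail` (data frame: observer, excluded, n directions out in both
#'   sessions).
#' @export
random_responder_null <- function(n_observers = 5000, series,
                                  config = session_config(), seed = 1,
                                  sessions = 2, progress_every = 0) {
  if (n_observers == 0) {
    return(list(fraction_excluded = NaN, n_excluded = 0L, n_observers = 0L,
                detail = data.frame(observer = integer(),
                                    excluded = logical(),
                                    n_directions_both_out = integer())))
  }
  rr <- random_responder()
  directions <- config$directions
  excluded <- logical(n_observers)
  n_both <- integer(n_observers)
  max_de <- vapply(directions, function(d) max_test_delta_e(series, d),
                   numeric(1))
  for (i in seq_len(n_observers)) {
    out_mat <- matrix(FALSE, nrow = sessions, ncol = length(directions),
                      dimnames = list(NULL, directions))
    for (ss in seq_len(sessions)) {
      log <- run_session(rr, "shuffled", series, config,
                         seed = derive_seed(seed, i, ss),
                         observer_id = paste0("rr", i), session = ss)
      est <- session_thresholds(log, series)
      out_mat[ss, est$direction] <- !est$in_range
    }
    both <- apply(out_mat, 2, all)
    n_both[i] <- sum(both)
    excluded[i] <- any(both)
    if (progress_every > 0 && i %% progress_every == 0) {
      message(sprintf("random-responder null: %d / %d (excluded so far: %.4f)",
                      i, n_observers, mean(excluded[seq_len(i)])))
    }
  }
  list(fraction_excluded = mean(excluded), n_excluded = sum(excluded),
       n_observers = n_observers,
       detail = data.frame(observer = seq_len(n_observers),
                           excluded = excluded,
                           n_directions_both_out = n_both))
}
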