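# Fixation statistics over kept trials: counts, joint spatial spread,
# cross-interval reflectance / location overlap with trial-shuffled
# permutation nulls, per-reflectance fixation distributions, and rank
# correlations with thresholds. Trials are represented as a single data
# frame of attributed fixations with a `trial` column.

#' Mean fixation counts per interval
#'
#' @param fixations Attributed fixation data frame with `trial` and
#'   `interval` columns (kept trials only).
#' @param trials Vector of kept trial ids (defaults to those present).
#' @return Data frame: `interval`, `mean_count`, `se`, `n_trials`. Trials
#'   with no fixation in an interval count 0.
#' @export
fixation_counts <- function(fixations, trials = unique(fixations$trial)) {
  if (!length(trials)) {
    return(data.frame(interval = character(), mean_count = numeric(),
                      se = numeric(), n_trials = integer()))
  }
  out <- lapply(c("target", "comp1", "comp2"), function(iv) {
    counts <- vapply(trials, function(tr) {
      sum(fixations$trial == tr & fixations$interval == iv)
    }, numeric(1))
    data.frame(interval = iv, mean_count = mean(counts),
               se = stats::sd(counts) / sqrt(length(counts)),
               n_trials = length(counts))
  })
  do.call(rbind, out)
}

#' Joint spatial spread of fixations
#'
#' Pools all fixation centroids of an interval across trials and returns
#' `sqrt(sd_x^2 + sd_y^2)`. Population SD (divide by n) convention; recorded
#' here so either convention is reproducible.
#'
#' @param fixations Attributed fixation data frame (kept trials).
#' @param interval Interval name.
#' @return Scalar degrees, or `NA` (flagged via attribute `reason`) with
#'   fewer than 2 fixations.
#' @export
joint_spread <- function(fixations, interval) {
  sub <- fixations[fixations$interval == interval, ]
  if (nrow(sub) < 2) {
    return(structure(NA_real_, reason = "fewer than 2 fixations"))
  }
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  sqrt(psd(sub$x)^2 + psd(sub$y)^2)
}

# per-trial overlap of unique reflectances: |comp n target| / |comp|
.trial_reflectance_overlap <- function(comp_refl, target_refl) {
  cu <- unique(comp_refl[!is.na(comp_refl)])
  tu <- unique(target_refl[!is.na(target_refl)])
  if (!length(cu)) return(NA_real_)
  length(intersect(cu, tu)) / length(cu)
}

#' Cross-interval reflectance overlap
#'
#' Per trial and comparison interval: the proportion of unique surface
#' reflectances fixated in the comparison interval that were also fixated in
#' the target interval; averaged across kept trials. Trials with no
#' attributed comparison-interval fixation are skipped for that interval.
#'
#' @param fixations Attributed fixation data frame (kept trials).
#' @return Data frame: `comparison` (`comp1`/`comp2`), `overlap`, `n_trials`
#'   (trials contributing).
#' @export
reflectance_overlap <- function(fixations) {
  trials <- unique(fixations$trial)
  out <- lapply(c("comp1", "comp2"), function(cv) {
    vals <- vapply(trials, function(tr) {
      sub <- fixations[fixations$trial == tr, ]
      .trial_reflectance_overlap(sub$reflectance[sub$interval == cv],
                                 sub$reflectance[sub$interval == "target"])
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    data.frame(comparison = cv,
               overlap = if (length(vals)) mean(vals) else NA_real_,
               n_trials = length(vals))
  })
  do.call(rbind, out)
}

#' Cross-interval location overlap
#'
#' Per trial and comparison interval: the fraction of comparison-interval
#' fixations whose centroid lies within `radius_deg` of any target-interval
#' fixation centroid; averaged across kept trials. A radius-based
#' reconstruction of location overlap (the criterion radius is a free
#' parameter).
#'
#' @param fixations Attributed fixation data frame (kept trials).
#' @param radius_deg Match radius in degrees.
#' @return Data frame: `comparison`, `overlap`, `n_trials`.
#' @export
location_overlap <- function(fixations, radius_deg = 1.5) {
  trials <- unique(fixations$trial)
  out <- lapply(c("comp1", "comp2"), function(cv) {
    vals <- vapply(trials, function(tr) {
      sub <- fixations[fixations$trial == tr, ]
      cs <- sub[sub$interval == cv, ]
      ts <- sub[sub$interval == "target", ]
      if (!nrow(cs)) return(NA_real_)
      if (!nrow(ts)) return(0)
      mean(vapply(seq_len(nrow(cs)), function(i) {
        any(sqrt((cs$x[i] - ts$x)^2 + (cs$y[i] - ts$y)^2) <= radius_deg)
      }, logical(1)))
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    data.frame(comparison = cv,
               overlap = if (length(vals)) mean(vals) else NA_real_,
               n_trials = length(vals))
  })
  do.call(rbind, out)
}

#' Trial-shuffled null for an overlap statistic
#'
#' Recomputes an overlap statistic after permuting the assignment of
#' comparison-interval fixation sets to target intervals across trials, with
#' an independent permutation for each comparison interval: the chance level
#' of overlap given each observer's aggregate fixation behavior.
#'
#' @param fixations Attributed fixation data frame (kept trials).
#' @param statistic Function of a fixation data frame returning the overlap
#'   table ([reflectance_overlap()] or [location_overlap()]).
#' @param seed Integer seed for the permutations.
#' @return The statistic's table computed on the shuffled pairing.
#' @export
shuffled_null <- function(fixations, statistic = reflectance_overlap,
                          seed = 1) {
  trials <- unique(fixations$trial)
  if (length(trials) < 2) stop("need >= 2 kept trials to shuffle", call. = FALSE)
  with_seed(seed, {
    shuffled <- fixations
    for (cv in c("comp1", "comp2")) {
      perm <- stats::setNames(resample(trials), trials)
      idx <- shuffled$interval == cv
      shuffled$trial[idx] <- unname(perm[as.character(fixations$trial[idx])])
    }
    statistic(shuffled)
  })
}

#' Relative fixation proportions per reflectance
#'
#' Normalized histogram of attributed fixations over the reflectance set,
#' per interval; untiled fixations are excluded from the denominator and
#' counted separately.
#'
#' @param fixations Attributed fixation data frame (kept trials).
#' @param refl_names Full reflectance name set (defines the bins).
#' @return Data frame: `interval`, one row per reflectance with `proportion`,
#'   plus attribute `n_untiled`.
#' @export
per_reflectance_distribution <- function(fixations, refl_names) {
  out <- lapply(c("target", "comp1", "comp2"), function(iv) {
    sub <- fixations[fixations$interval == iv, ]
    attributed <- sub$reflectance[!is.na(sub$reflectance)]
    counts <- table(factor(attributed, levels = refl_names))
    prop <- if (length(attributed)) as.numeric(counts) / length(attributed)
            else rep(NA_real_, length(refl_names))
    data.frame(interval = iv, reflectance = refl_names, proportion = prop)
  })
  res <- do.call(rbind, out)
  attr(res, "n_untiled") <- sum(is.na(fixations$reflectance))
  res
}

#' Spearman rank correlation with a permutation p value
#'
#' Rank correlation between a per-observer fixation statistic and the
#' per-observer mean threshold. For n <= 8 the p value is exact (full
#' permutation enumeration); for larger n it uses the t approximation.
#'
#' @param statistic Numeric vector (per observer).
#' @param threshold Numeric vector (same observers).
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
correlate_with_thresholds <- function(statistic, threshold) {
  stopifnot(length(statistic) == length(threshold))
  ok <- is.finite(statistic) & is.finite(threshold)
  x <- statistic[ok]; y <- threshold[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined (ties only)"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx[p], ry))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# all permutations of 1..n (n <= 8)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}
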