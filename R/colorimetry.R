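# Spectra -> CIE XYZ -> CIELUV, Euclidean Delta E, and construction of the
# experimental illuminant series (a daylight-metamer target plus four series
# of test illuminants along / orthogonal to the daylight locus).

#' Convert a spectrum to CIE XYZ tristimulus values
#'
#' Trapezoid inner product of the spectrum (times an illuminant, for surface
#' reflectances) with the CIE 1931 2-degree color-matching functions. The
#' color-matching functions are interpolated linearly onto the spectrum's
#' wavelength grid over the region of overlap.
#'
#' @param s A [spectrum()]. If `s` is a reflectance, `illuminant` must be
#'   supplied and the integrand is the product of the two.
#' @param illuminant Optional illuminant [spectrum()] under which a surface
#'   reflectance is viewed.
#' @return Named numeric vector `c(X, Y, Z)` (Y in relative luminance units).
#' @export
spectrum_to_xyz <- function(s, illuminant = NULL) {
  stopifnot(is_spectrum(s))
  vals <- s$values
  wl <- s$wavelengths
  if (!is.null(illuminant)) {
    stopifnot(is_spectrum(illuminant))
    iv <- resample_spectrum(illuminant, wl)
    vals <- vals * iv
  } else if (s$type == "reflectance") {
    stop("a reflectance spectrum needs an illuminant for XYZ conversion",
         call. = FALSE)
  }
  cmf_wl <- grid_wavelengths()
  lo <- max(min(wl), min(cmf_wl))
  hi <- min(max(wl), max(cmf_wl))
  if (lo >= hi) {
    stop("wavelength grid does not overlap the color-matching-function support",
         call. = FALSE)
  }
  keep <- wl >= lo & wl <= hi
  wl <- wl[keep]
  vals <- vals[keep]
  if (length(wl) < 2) {
    stop("wavelength grid does not overlap the color-matching-function support",
         call. = FALSE)
  }
  cmf <- apply(.cie1931_cmf, 2, function(col) {
    stats::approx(cmf_wl, col, xout = wl, rule = 1)$y
  })
  w <- trapezoid_weights(wl)
  xyz <- as.numeric(crossprod(cmf, vals * w))
  names(xyz) <- c("X", "Y", "Z")
  xyz
}

# Linear interpolation of a spectrum onto a target grid (error outside support).
resample_spectrum <- function(s, wl_out) {
  out <- stats::approx(s$wavelengths, s$values, xout = wl_out, rule = 1)$y
  if (any(is.na(out))) {
    stop("spectrum does not cover the requested wavelength range", call. = FALSE)
  }
  out
}

trapezoid_weights <- function(wl) {
  n <- length(wl)
  d <- diff(wl)
  w <- numeric(n)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

#' CIE 1976 u', v' chromaticity from XYZ
#'
#' @param xyz Named or positional numeric vector `(X, Y, Z)`.
#' @return Named numeric vector `c(u = u', v = v')`.
#' @export
xyz_to_upvp <- function(xyz) {
  d <- xyz[[1]] + 15 * xyz[[2]] + 3 * xyz[[3]]
  c(u = 4 * xyz[[1]] / d, v = 9 * xyz[[2]] / d)
}

#' u', v' chromaticity from CIE xy
#'
#' @param xy Numeric vector `(x, y)`.
#' @return Named numeric vector `c(u, v)`.
#' @export
xy_to_upvp <- function(xy) {
  d <- -2 * xy[[1]] + 12 * xy[[2]] + 3
  c(u = 4 * xy[[1]] / d, v = 9 * xy[[2]] / d)
}

upvp_to_xy <- function(uv) {
  d <- 6 * uv[[1]] - 16 * uv[[2]] + 12
  c(x = 9 * uv[[1]] / d, y = 4 * uv[[2]] / d)
}

#' Convert XYZ to CIELUV
#'
#' Standard forward transform with an explicit white point: `L*` from `Y/Yn`
#' (116 f - 16 with the two-branch cube-root function), `u* = 13 L* (u' -
#' u'_n)`, `v* = 13 L* (v' - v'_n)`.
#'
#' @param xyz Tristimulus vector `(X, Y, Z)`.
#' @param white White-point tristimulus vector; `white[2]` (Y) must be > 0.
#' @return Named numeric vector `c(L, u, v)`.
#' @export
xyz_to_luv <- function(xyz, white) {
  if (white[[2]] <= 0) stop("white point must have Y > 0", call. = FALSE)
  yr <- xyz[[2]] / white[[2]]
  eps <- (6 / 29)^3
  L <- if (yr > eps) 116 * yr^(1 / 3) - 16 else (29 / 3)^3 * yr
  uvn <- xyz_to_upvp(white)
  if (xyz[[1]] + 15 * xyz[[2]] + 3 * xyz[[3]] <= 0) {
    uv <- uvn # black: chromaticity undefined, u* = v* = 0 by convention
  } else {
    uv <- xyz_to_upvp(xyz)
  }
  c(L = L, u = 13 * L * (uv[[1]] - uvn[[1]]), v = 13 * L * (uv[[2]] - uvn[[2]]))
}

#' Convert CIELUV back to XYZ
#'
#' Inverse of [xyz_to_luv()] under the same white point.
#'
#' @param luv Numeric vector `(L, u, v)`.
#' @param white White-point tristimulus vector.
#' @return Named numeric vector `c(X, Y, Z)`.
#' @export
luv_to_xyz <- function(luv, white) {
  if (white[[2]] <= 0) stop("white point must have Y > 0", call. = FALSE)
  L <- luv[[1]]
  eps <- (6 / 29)^3
  kappa <- (29 / 3)^3
  yr <- if (L > kappa * eps) ((L + 16) / 116)^3 else L / kappa
  Y <- yr * white[[2]]
  if (L <= 0) return(c(X = 0, Y = 0, Z = 0))
  uvn <- xyz_to_upvp(white)
  up <- luv[[2]] / (13 * L) + uvn[[1]]
  vp <- luv[[3]] / (13 * L) + uvn[[2]]
  X <- Y * 9 * up / (4 * vp)
  Z <- Y * (12 - 3 * up - 20 * vp) / (4 * vp)
  c(X = X, Y = Y, Z = unname(Z))
}

#' CIELUV color difference
#'
#' Euclidean distance over all three CIELUV dimensions; both coordinates must
#' have been computed under the same white point.
#'
#' @param a,b CIELUV vectors `(L, u, v)`.
#' @return Delta E (non-negative scalar).
#' @export
delta_e <- function(a, b) {
  sqrt((a[[1]] - b[[1]])^2 + (a[[2]] - b[[2]])^2 + (a[[3]] - b[[3]])^2)
}

#' CIE daylight spectrum at a correlated color temperature
#'
#' Reconstructs a daylight spectral power distribution as `S0 + M1 S1 + M2 S2`
#' from the CIE daylight basis, with the weights determined by the daylight
#' chromaticity at the requested CCT.
#'
#' @param cct Correlated color temperature in Kelvin.
#' @return An illuminant [spectrum()] on the working grid (unnormalized).
#' @export
daylight_spectrum <- function(cct) {
  xy <- daylight_chromaticity(cct)
  m <- 0.0241 + 0.2562 * xy[["x"]] - 0.7341 * xy[["y"]]
  m1 <- (-1.3515 - 1.7703 * xy[["x"]] + 5.9114 * xy[["y"]]) / m
  m2 <- (0.0300 - 31.4424 * xy[["x"]] + 30.0717 * xy[["y"]]) / m
  vals <- .cie_daylight_basis %*% c(1, m1, m2)
  spectrum(grid_wavelengths(), pmax(as.numeric(vals), 0), "illuminant")
}

# Tristimulus of the three daylight basis columns (trapezoid inner product on
# the shared native grid); used to solve basis weights for a target
# chromaticity analytically.
daylight_basis_xyz <- function() {
  w <- trapezoid_weights(grid_wavelengths())
  crossprod(.cie1931_cmf, .cie_daylight_basis * w) # 3 x 3: rows X,Y,Z; cols S0,S1,S2
}

# Smooth mid-wavelength perturbation basis: extends the reachable chromaticity
# gamut beyond what the two daylight principal components span (needed for the
# far steps of the locus-orthogonal directions) while keeping spectra smooth.
perturbation_basis <- function() {
  100 * exp(-0.5 * ((grid_wavelengths() - 530) / 45)^2)
}

# Solve S0 + m3 G + m1 S1 + m2 S2 for a requested xy chromaticity, scaled to
# luminance Y. The perturbation weight m3 defaults to 0 (pure daylight basis);
# when that spectrum would have negative power, the smallest |m3| restoring
# non-negativity is used. Errors if no weight in the search range works.
spectrum_from_chromaticity <- function(xy, Y_out, context = "") {
  B <- daylight_basis_xyz()
  w <- trapezoid_weights(grid_wavelengths())
  G <- perturbation_basis()
  Gxyz <- as.numeric(crossprod(.cie1931_cmf, G * w))
  Ti <- colSums(B)
  A <- rbind(
    c(B["xbar", 2] - xy[[1]] * Ti[2], B["xbar", 3] - xy[[1]] * Ti[3]),
    c(B["ybar", 2] - xy[[2]] * Ti[2], B["ybar", 3] - xy[[2]] * Ti[3])
  )
  solve_for <- function(m3) {
    base <- B[, 1] + m3 * Gxyz # X,Y,Z of S0 + m3 G
    Tb <- sum(base)
    b <- c(xy[[1]] * Tb - base[1], xy[[2]] * Tb - base[2])
    m <- solve(A, b)
    as.numeric(.cie_daylight_basis %*% c(1, m)) + m3 * G
  }
  vals <- NULL
  for (m3 in c(0, as.vector(rbind(1, -1) %o% seq(0.25, 4, by = 0.25)))) {
    cand <- solve_for(m3)
    if (min(cand) >= 0) { vals <- cand; break }
  }
  if (is.null(vals)) {
    stop(sprintf("series-construction error%s: unreachable chromaticity",
                 if (nzchar(context)) paste0(" (", context, ")") else ""),
         call. = FALSE)
  }
  s <- spectrum(grid_wavelengths(), vals, "illuminant")
  y <- spectrum_to_xyz(s)[["Y"]]
  spectrum(grid_wavelengths(), vals * Y_out / y, "illuminant")
}

# Dense sampling of the daylight locus in u'v', indexed by mired (1e6/CCT).
# Chromaticities are those of the reconstructed daylight spectra integrated on
# the working grid (not the CIE chromaticity polynomial), so the locus passes
# exactly through the chromaticity of the reconstructed target spectrum.
daylight_locus_upvp <- function(cct_anchor, n = 2001) {
  mired <- sort(unique(c(seq(1e6 / 25000, 1e6 / 4000, length.out = n),
                         1e6 / cct_anchor)))
  uv <- t(vapply(1e6 / mired, function(cc) {
    xyz_to_upvp(spectrum_to_xyz(daylight_spectrum(cc)))
  }, numeric(2)))
  list(mired = mired, u = uv[, 1], v = uv[, 2])
}

#' Build the experimental illuminant series
#'
#' One target illuminant (a daylight metamer at the requested CCT, scaled to
#' `Y = 100`) plus `n_steps` test illuminants in each requested chromatic
#' direction. Blue and yellow follow the daylight locus (arc-length spaced in
#' u'v'); red and green move orthogonally to the locus tangent at the target.
#' All spectra are scaled to the target luminance, so nominal step k sits
#' approximately k CIELUV Delta E units from the target (white point: the
#' target's own XYZ).
#'
#' @param cct Target correlated color temperature in Kelvin.
#' @param n_steps Number of test illuminants per direction.
#' @param directions Subset of `c("blue", "yellow", "red", "green")`.
#' @param step_delta_e Spacing of consecutive nominal steps in Delta E.
#' @return An object of class `illuminant_series` with fields `target`
#'   (spectrum), `target_xyz` (white point), `tests` (named list of spectra
#'   keyed `"direction.step"`), and `lookup` (data frame with `direction`,
#'   `nominal_step`, `actual_delta_e`).
#' @export
build_illuminant_series <- function(cct = 6700, n_steps = 50,
                                    directions = c("blue", "yellow", "red", "green"),
                                    step_delta_e = 1) {
  stopifnot(n_steps >= 1,
            all(directions %in% c("blue", "yellow", "red", "green")))
  target <- daylight_spectrum(cct)
  xyz0 <- spectrum_to_xyz(target)
  target <- spectrum(target$wavelengths, target$values * 100 / xyz0[["Y"]],
                     "illuminant")
  target_xyz <- spectrum_to_xyz(target)
  uv0 <- xyz_to_upvp(target_xyz)

  locus <- daylight_locus_upvp(cct)
  m0 <- 1e6 / cct
  i0 <- which.min(abs(locus$mired - m0))
  seg <- sqrt(diff(locus$u)^2 + diff(locus$v)^2)
  # signed arc length relative to the target (positive toward low CCT / yellow)
  arc <- c(0, cumsum(seg))
  arc <- arc - arc[i0]
  # locus tangent at the target, pointing toward yellow (increasing mired)
  j <- max(i0 - 5, 1); k <- min(i0 + 5, length(arc))
  tangent <- c(locus$u[k] - locus$u[j], locus$v[k] - locus$v[j])
  tangent <- tangent / sqrt(sum(tangent^2))
  normal <- c(tangent[2], -tangent[1])     # rotate -90 degrees
  if (normal[1] < 0) normal <- -normal     # red: toward higher u'
  duv <- step_delta_e / (13 * 100)         # 1 Delta E at L* = 100

  # chromaticity of nominal step k in a given direction
  step_uv <- function(direction, k) {
    s <- k * duv
    switch(direction,
      yellow = locus_point(locus, arc, s),
      blue   = locus_point(locus, arc, -s),
      red    = c(uv0[[1]], uv0[[2]]) + s * normal,
      green  = c(uv0[[1]], uv0[[2]]) - s * normal
    )
  }

  tests <- list()
  lookup <- data.frame(direction = character(), nominal_step = integer(),
                       actual_delta_e = numeric())
  target_luv <- xyz_to_luv(target_xyz, target_xyz)
  for (dir in directions) {
    for (k in seq_len(n_steps)) {
      uv <- step_uv(dir, k)
      xy <- upvp_to_xy(uv)
      sp <- spectrum_from_chromaticity(xy, 100,
                                       context = sprintf("%s step %d", dir, k))
      luv <- xyz_to_luv(spectrum_to_xyz(sp), target_xyz)
      tests[[paste(dir, k, sep = ".")]] <- sp
      lookup <- rbind(lookup, data.frame(direction = dir, nominal_step = k,
                                         actual_delta_e = delta_e(luv, target_luv)))
    }
  }
  structure(list(target = target, target_xyz = target_xyz,
                 tests = tests, lookup = lookup,
                 cct = cct, n_steps = n_steps, directions = directions),
            class = "illuminant_series")
}

# interpolate the locus at signed arc length s from the target
locus_point <- function(locus, arc, s) {
  if (s < min(arc) || s > max(arc)) {
    stop(sprintf("series-construction error: arc length %.4f outside daylight locus range", s),
         call. = FALSE)
  }
  c(stats::approx(arc, locus$u, xout = s)$y,
    stats::approx(arc, locus$v, xout = s)$y)
}

#' @export
print.illuminant_series <- function(x, ...) {
  cat(sprintf("<illuminant_series: D%d target + %d tests (%s), ~%g dE steps>\n",
              round(x$cct / 100), length(x$tests),
              paste(x$directions, collapse = "/"), 1))
  invisible(x)
}

#' Actual Delta E of a nominal step
#'
#' @param series An `illuminant_series`.
#' @param direction Chromatic direction.
#' @param step Nominal step (may be a vector).
#' @return Actual Delta E value(s) from the series lookup table.
#' @export
actual_delta_e <- function(series, direction, step) {
  lk <- series$lookup
  idx <- match(paste(direction, step), paste(lk$direction, lk$nominal_step))
  if (anyNA(idx)) stop("unknown direction/step in series lookup", call. = FALSE)
  lk$actual_delta_e[idx]
}

#' Maximal test Delta E of a direction
#'
#' The actual Delta E of the largest nominal step: the substitution value for
#' out-of-range thresholds and the in-range boundary.
#'
#' @param series An `illuminant_series`.
#' @param direction Chromatic direction.
#' @return Scalar Delta E.
#' @export
max_test_delta_e <- function(series, direction) {
  lk <- series$lookup
  max(lk$actual_delta_e[lk$direction == direction])
}

#' Retrieve a test illuminant spectrum
#'
#' @param series An `illuminant_series`.
#' @param direction Chromatic direction, or `"target"`.
#' @param step Nominal step (ignored for the target).
#' @return A [spectrum()].
#' @export
series_spectrum <- function(series, direction, step = NULL) {
  if (direction == "target") return(series$target)
  sp <- series$tests[[paste(direction, step, sep = ".")]]
  if (is.null(sp)) stop("unknown direction/step in series", call. = FALSE)
  sp
}

#' Write an illuminant series to CSV
#'
#' One row per spectrum: `direction`, `nominal_step`, `actual_delta_e`, then
#' one column per wavelength. The target row has `direction = "target"`,
#' `nominal_step = 0`, `actual_delta_e = 0`.
#'
#' @param series An `illuminant_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_illuminant_series <- function(series, path) {
  wl <- series$target$wavelengths
  rows <- rbind(
    data.frame(direction = "target", nominal_step = 0L, actual_delta_e = 0,
               t(series$target$values)),
    do.call(rbind, lapply(seq_len(nrow(series$lookup)), function(i) {
      key <- paste(series$lookup$direction[i], series$lookup$nominal_step[i], sep = ".")
      data.frame(direction = series$lookup$direction[i],
                 nominal_step = series$lookup$nominal_step[i],
                 actual_delta_e = series$lookup$actual_delta_e[i],
                 t(series$tests[[key]]$values))
    }))
  )
  names(rows)[-(1:3)] <- paste0("w", wl)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
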