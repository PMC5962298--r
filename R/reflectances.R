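# The 14-sample surface reflectance set. The originals are unprinted, so the
# set is regenerated with the stated structure: samples spanning the hue
# circle plus near-neutrals, including four high-luminance low-saturation
# members (pale-green, pale-blue, light-gray, pale-orange) that rank as the
# four brightest surfaces under the target illuminant.

#' Generate the 14-sample reflectance set
#'
#' Smooth reflectances built from Gaussian bumps on the working wavelength
#' grid: ten chromatic samples with centers spread across the spectrum (plus a
#' two-lobed purple and two darker neutrals) and four designated pale samples
#' with a high base reflectance and a gentle tint. The seed jitters bump
#' centers and widths slightly; the set is deterministic given the seed.
#'
#' @param seed Integer seed.
#' @return Named list of 14 reflectance [spectrum()] objects. The pale
#'   members are named `pale_green`, `pale_blue`, `light_gray`, `pale_orange`.
#' @export
make_reflectance_set <- function(seed = 1) {
  wl <- grid_wavelengths()
  bump <- function(center, width, amp, base = 0.05) {
    pmin(1, pmax(0, base + amp * exp(-0.5 * ((wl - center) / width)^2)))
  }
  jit <- function(x, sd) x + stats::rnorm(1, sd = sd)
  pale <- function(center, width, tint, base = 0.62) {
    pmin(1, base + tint * exp(-0.5 * ((wl - center) / width)^2))
  }
  refl <- with_seed(seed, list(
    pale_green  = pale(jit(540, 3), 60, 0.12),
    pale_blue   = pale(jit(470, 3), 55, 0.12),
    light_gray  = rep(0.66, length(wl)),
    pale_orange = pale(jit(600, 3), 70, 0.12),
    blue        = bump(jit(455, 4), 32, 0.45),
    cyan        = bump(jit(495, 4), 30, 0.42),
    green       = bump(jit(535, 4), 32, 0.45),
    yellow      = bump(jit(575, 4), 38, 0.42),
    orange      = bump(jit(610, 4), 38, 0.45),
    red         = bump(jit(650, 4), 42, 0.48),
    violet      = bump(jit(420, 4), 28, 0.42),
    purple      = pmin(1, bump(jit(430, 4), 30, 0.30) +
                          0.30 * exp(-0.5 * ((wl - jit(670, 4)) / 35)^2)),
    dark_gray   = rep(0.18, length(wl)),
    mid_gray    = rep(0.33, length(wl))
  ))
  lapply(refl, function(v) spectrum(wl, v, "reflectance"))
}

#' Names of the designated pale (high-luminance) reflectances
#'
#' @return Character vector of length 4.
#' @export
pale_reflectance_names <- function() {
  c("pale_green", "pale_blue", "light_gray", "pale_orange")
}

#' Relative luminance of each reflectance under an illuminant
#'
#' @param refl Reflectance set from [make_reflectance_set()].
#' @param illuminant An illuminant [spectrum()].
#' @return Named numeric vector of Y values.
#' @export
reflectance_luminance <- function(refl, illuminant) {
  vapply(refl, function(r) spectrum_to_xyz(r, illuminant)[["Y"]], numeric(1))
}
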