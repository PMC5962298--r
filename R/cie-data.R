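# CIE reference tables on the working wavelength grid (400-700 nm, 10 nm).
# Values are the standard published tables, truncated to the grid used for
# the 31-sample spectral representation adopted throughout the package.

#' Working wavelength grid (nm)
#'
#' 400--700 nm in 10 nm steps: the 31-sample grid on which all spectra in the
#' package are represented.
#'
#' @return Numeric vector of 31 wavelengths in nm.
#' @export
grid_wavelengths <- function() seq(400, 700, by = 10)

# CIE 1931 2-degree standard observer color-matching functions.
.cie1931_cmf <- matrix(c(
  # xbar,   ybar,   zbar
  0.0143, 0.0004, 0.0679,
  0.0435, 0.0012, 0.2074,
  0.1344, 0.0040, 0.6456,
  0.2839, 0.0116, 1.3856,
  0.3483, 0.0230, 1.7471,
  0.3362, 0.0380, 1.7721,
  0.2908, 0.0600, 1.6692,
  0.1954, 0.0910, 1.2876,
  0.0956, 0.1390, 0.8130,
  0.0320, 0.2080, 0.4652,
  0.0049, 0.3230, 0.2720,
  0.0093, 0.5030, 0.1582,
  0.0633, 0.7100, 0.0782,
  0.1655, 0.8620, 0.0422,
  0.2904, 0.9540, 0.0203,
  0.4334, 0.9950, 0.0087,
  0.5945, 0.9950, 0.0039,
  0.7621, 0.9520, 0.0021,
  0.9163, 0.8700, 0.0017,
  1.0263, 0.7570, 0.0011,
  1.0622, 0.6310, 0.0008,
  1.0026, 0.5030, 0.0003,
  0.8544, 0.3810, 0.0002,
  0.6424, 0.2650, 0.0000,
  0.4479, 0.1750, 0.0000,
  0.2835, 0.1070, 0.0000,
  0.1649, 0.0610, 0.0000,
  0.0874, 0.0320, 0.0000,
  0.0468, 0.0170, 0.0000,
  0.0227, 0.0082, 0.0000,
  0.0114, 0.0041, 0.0000
), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("xbar", "ybar", "zbar")))

# CIE daylight basis functions S0, S1, S2 (mean daylight vector plus the two
# principal components of daylight variation).
.cie_daylight_basis <- matrix(c(
  #   S0,    S1,    S2
   94.80, 43.40, -1.10,
  104.80, 46.30, -0.50,
  105.90, 43.90, -0.70,
   96.80, 37.10, -1.20,
  113.90, 36.70, -2.60,
  125.60, 35.90, -2.90,
  125.50, 32.60, -2.80,
  121.30, 27.90, -2.60,
  121.30, 24.30, -2.60,
  113.50, 20.10, -1.80,
  113.10, 16.20, -1.50,
  110.80, 13.20, -1.30,
  106.50,  8.60, -1.20,
  108.80,  6.10, -1.00,
  105.30,  4.20, -0.50,
  104.40,  1.90, -0.30,
  100.00,  0.00,  0.00,
   96.00, -1.60,  0.20,
   95.10, -3.50,  0.50,
   89.10, -3.50,  2.10,
   90.50, -5.80,  3.20,
   90.30, -7.20,  4.10,
   88.40, -8.60,  4.70,
   84.00, -9.50,  5.10,
   85.10, -10.90, 6.70,
   81.90, -10.70, 7.30,
   82.60, -12.00, 8.60,
   84.90, -14.00, 9.80,
   81.30, -13.60, 10.20,
   71.90, -12.00,  8.30,
   74.30, -13.30,  9.60
), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("S0", "S1", "S2")))

#' CIE 1931 color-matching functions on the working grid
#'
#' @return Data frame with columns `wavelength`, `xbar`, `ybar`, `zbar`.
#' @export
cie1931_cmf <- function() {
  data.frame(wavelength = grid_wavelengths(), .cie1931_cmf)
}

#' CIE daylight basis functions on the working grid
#'
#' @return Data frame with columns `wavelength`, `S0`, `S1`, `S2`.
#' @export
cie_daylight_basis <- function() {
  data.frame(wavelength = grid_wavelengths(), .cie_daylight_basis)
}

#' Daylight chromaticity at a correlated color temperature
#'
#' CIE method: the daylight-locus chromaticity `(x_D, y_D)` as a cubic
#' polynomial in reciprocal CCT, with the low- and high-CCT branches switching
#' at 7000 K.
#'
#' @param cct Correlated color temperature in Kelvin (4000--25000).
#' @return Named numeric vector `c(x, y)`.
#' @export
daylight_chromaticity <- function(cct) {
  stopifnot(is.numeric(cct), cct >= 4000, cct <= 25000)
  t3 <- 1e9 / cct^3; t2 <- 1e6 / cct^2; t1 <- 1e3 / cct
  xd <- ifelse(cct <= 7000,
               0.244063 + 0.09911 * t1 + 2.9678 * t2 - 4.6070 * t3,
               0.237040 + 0.24748 * t1 + 1.9018 * t2 - 2.0064 * t3)
  yd <- -3.000 * xd^2 + 2.870 * xd - 0.275
  c(x = unname(xd), y = unname(yd))
}
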