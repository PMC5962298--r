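# Shared fixtures, built once per test run. The illuminant series is the
# expensive one (~1 s); everything downstream reuses it.

the_series <- build_illuminant_series()
the_grid <- make_tile_grid()
the_refl <- make_reflectance_set(seed = 1)

# independent trapezoid-integration oracle for spectrum -> XYZ
oracle_xyz <- function(values, wavelengths = grid_wavelengths()) {
  cmf <- cie1931_cmf()
  out <- numeric(3)
  for (j in 1:3) {
    f <- values * cmf[[j + 1]]
    acc <- 0
    for (i in seq_len(length(wavelengths) - 1)) {
      acc <- acc + (f[i] + f[i + 1]) / 2 * (wavelengths[i + 1] - wavelengths[i])
    }
    out[j] <- acc
  }
  names(out) <- c("X", "Y", "Z")
  out
}

# textbook CIELUV forward transform oracle
oracle_luv <- function(xyz, white) {
  upvp <- function(v) {
    d <- v[1] + 15 * v[2] + 3 * v[3]
    c(4 * v[1] / d, 9 * v[2] / d)
  }
  yr <- xyz[2] / white[2]
  L <- if (yr > (6 / 29)^3) 116 * yr^(1 / 3) - 16 else (29 / 3)^3 * yr
  uv <- upvp(xyz); uvn <- upvp(white)
  c(L, 13 * L * (uv[1] - uvn[1]), 13 * L * (uv[2] - uvn[2]))
}
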