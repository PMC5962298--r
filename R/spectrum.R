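#' Spectral distribution
#'
#' Constructs a `spectrum` object: a sampled spectral power distribution
#' (illuminant) or spectral reflectance function (surface).
#'
#' @param wavelengths Strictly increasing wavelengths in nm.
#' @param values Spectral values; reflectances must lie in `[0, 1]`,
#'   illuminant power must be non-negative.
#' @param type `"illuminant"` or `"reflectance"`.
#' @return An object of class `spectrum` with fields `wavelengths`, `values`,
#'   `type`.
#' @export
spectrum <- function(wavelengths, values, type = c("illuminant", "reflectance")) {
  type <- match.arg(type)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have equal length", call. = FALSE)
  }
  if (length(wavelengths) < 2 || any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing (>= 2 samples)", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("spectral values must be finite", call. = FALSE)
  if (type == "reflectance" && (any(values < 0) || any(values > 1))) {
    stop("reflectance values must lie in [0, 1]", call. = FALSE)
  }
  if (type == "illuminant" && any(values < 0)) {
    stop("illuminant values must be non-negative", call. = FALSE)
  }
  structure(list(wavelengths = wavelengths, values = values, type = type),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d samples, %g-%g nm>\n",
              x$type, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")
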