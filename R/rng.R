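#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded generators compose without clobbering each
#' other.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  code
}

#' Derive a child seed from a parent seed and index coordinates
#'
#' Deterministic mixing of the parent seed with any number of integer
#' coordinates (observer, session, trial, ...); results stay below 2^31.
#'
#' @param seed Parent seed.
#' @param ... Integer coordinates.
#' @return Integer child seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  parts <- c(seed, unlist(list(...)))
  x <- 0
  # multipliers kept small enough that every product stays below 2^53,
  # so the modular arithmetic is exact in doubles
  for (p in parts) {
    x <- (x * 69069 + (as.numeric(p) %% m) * 40503 + 12345) %% m
    x <- (x * 69069 + 1) %% m
  }
  as.integer(x)
}
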