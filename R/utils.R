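#' Derive a named substream seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams, so that e.g. the e-nose and spectral renderings of a study can
#' be regenerated independently and every pipeline stage logs a reproducible
#' seed. The derivation is a small integer hash kept below 2^31.
#'
#' @param seed master integer seed.
#' @param name character substream name.
#' @param index optional non-negative integer within the substream.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
substream_seed <- function(seed, name, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  s <- (abs(seed) %% 2147483647) * 69069 %% 2147483647
  as.integer((s + h * 40503 + index * 7919) %% 2147483647)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Round half-up to a fixed number of decimals
#'
#' Identification rates are conventionally reported with ordinary half-up
#' rounding (104/105 -> 99.05), not banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Identification rate as a reported percentage
#'
#' The study's accuracy metric: `100 * correct / total`, rounded half-up to
#' two decimals for reporting (e.g. 104/105 -> 99.05, 33/35 -> 94.29).
#'
#' @param correct number of correctly identified samples.
#' @param total number of samples.
#' @return percentage, rounded to 2 decimals.
#' @export
identification_rate <- function(correct, total) {
  stopifnot(total > 0, correct >= 0, correct <= total)
  round_half_up(100 * correct / total, 2)
}

logistic_curve <- function(day, floor, ceiling, midpoint, steepness) {
  floor + (ceiling - floor) / (1 + exp(-steepness * (day - midpoint)))
}
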