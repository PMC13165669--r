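#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft mvfft rnorm runif sd quantile median coef lm approx
#'   setNames nextn
#' @importFrom utils head tail
NULL

## Error helpers ---------------------------------------------------------

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("radarecg_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("radarecg_data_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("radarecg_format_error", "error")))
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_data(what, " contains non-finite values")
  invisible(x)
}

## Seed plumbing ---------------------------------------------------------
##
## All randomness flows from one integer seed.  Child streams are derived
## by hashing (seed, key) so that subject draws, noise draws and shuffles
## are independently reproducible regardless of evaluation order.

#' Derive a reproducible child seed from a parent seed and a key
#'
#' A small FNV-style integer hash over the parent seed and a string key,
#' reduced modulo 2^31 - 1. Used so that every stochastic component of the
#' simulator consumes its own independent, named random stream.
#'
#' @param seed integer parent seed.
#' @param key character key naming the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  ## Lehmer-style mixing; the multiplier keeps h * 69069 + b < 2^53 so the
  ## arithmetic stays exact in doubles.
  h <- 113
  bytes <- c(utf8ToInt(as.character(key)), 255,
             as.integer(seed) %% 256L,
             (as.integer(seed) %/% 256L) %% 256L,
             (as.integer(seed) %/% 65536L) %% 256L,
             (as.integer(seed) %/% 16777216L) %% 256L)
  for (b in bytes) {
    h <- (h * 69069 + b + 1) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Misc ------------------------------------------------------------------

znorm <- function(x) {
  s <- sd(x)
  if (s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

periodogram_peak_freq <- function(x, fs) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))[seq_len(floor(n / 2))]
  freqs <- (seq_len(floor(n / 2)) - 1) * fs / n
  freqs[which.max(sp)]
}

## Amplitude of the DFT at the bin nearest `freq` (single-sided scale).
tone_amplitude <- function(x, fs, freq) {
  n <- length(x)
  sp <- fft(x)
  bins <- (0:(n - 1)) * fs / n
  j <- which.min(abs(bins[seq_len(floor(n / 2) + 1)] - freq))
  2 * Mod(sp[j]) / n
}
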