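## Quadrature demodulation: four-quadrant arctangent phase extraction,
## unwrapping, and conversion of phase to chest displacement.

#' Arctangent demodulation of quadrature radar channels
#'
#' Computes the wrapped phase with the four-quadrant arctangent of
#' `(q, i)` (the literal Q/I ratio would lose quadrant information and
#' reintroduce the detection nulls quadrature reception exists to avoid),
#' unwraps it by cumulative +/- 2 pi correction wherever adjacent wrapped
#' differences exceed pi, and estimates the constant phase offset as the
#' mean of the unwrapped trace.
#'
#' @param i_chan,q_chan equal-length numeric channels.
#' @return An object of class `phase_trace` with `wrapped` (rad, in
#'   `(-pi, pi]`), `unwrapped` (rad) and `theta_est` (rad).
#' @export
arctan_demodulate <- function(i_chan, q_chan) {
  if (length(i_chan) != length(q_chan))
    stop_data("channels must have equal length")
  degenerate <- which(i_chan == 0 & q_chan == 0)
  if (length(degenerate))
    stop_data("degenerate sample (I = Q = 0) at index ", degenerate[1])
  wrapped <- atan2(q_chan, i_chan)
  d <- diff(wrapped)
  corr <- cumsum(c(0, -2 * pi * (d > pi) + 2 * pi * (d < -pi)))
  unwrapped <- wrapped + corr
  structure(list(wrapped = wrapped, unwrapped = unwrapped,
                 theta_est = mean(unwrapped)),
            class = "phase_trace")
}

#' Convert an unwrapped phase trace to chest displacement
#'
#' Applies \eqn{x(t) = (\lambda_0 / 4\pi)(w(t) - \theta)}, with the constant
#' phase \eqn{\theta} taken from the trace-mean estimate, so the result is
#' zero-mean by construction.
#'
#' @param p a `phase_trace` from [arctan_demodulate()].
#' @param wavelength_mm radar wavelength, mm, positive.
#' @return Displacement, mm.
#' @export
phase_to_displacement <- function(p, wavelength_mm = 3) {
  if (wavelength_mm <= 0) stop_config("wavelength must be positive")
  wavelength_mm / (4 * pi) * (p$unwrapped - p$theta_est)
}

#' Echo envelope
#'
#' \eqn{A(t) = \sqrt{I^2(t) + Q^2(t)}}; constant and equal to the channel
#' amplitude in the noiseless quadrature model.
#'
#' @param i_chan,q_chan equal-length numeric channels.
#' @return Envelope amplitude, same length.
#' @export
envelope <- function(i_chan, q_chan) {
  if (length(i_chan) != length(q_chan))
    stop_data("channels must have equal length")
  sqrt(i_chan^2 + q_chan^2)
}

#' Demodulate every segment of a dataset
#'
#' Runs [arctan_demodulate()] and [phase_to_displacement()] on each segment,
#' storing the recovered displacement as `x_rec`.
#'
#' @param dataset a `radar_dataset`.
#' @return The dataset with `x_rec` added to each segment.
#' @export
demodulate_dataset <- function(dataset) {
  lambda <- dataset$cfg$wavelength_mm
  dataset$segments <- lapply(dataset$segments, function(seg) {
    p <- arctan_demodulate(seg$i_chan, seg$q_chan)
    seg$x_rec <- phase_to_displacement(p, lambda)
    seg
  })
  dataset
}
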