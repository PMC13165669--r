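## Synthetic ECG: five Gaussian bumps (P, Q, R, S, T) on an accumulated
## cardiac phase, McSharry-style, with AR(1)-correlated lognormal RR
## intervals.  Stands in for electrode ground truth and yields exact
## R-peak times for downstream localization metrics.

#' ECG model parameters
#'
#' Parameters of the five-Gaussian phase-domain ECG model. Each beat spans
#' one cardiac cycle of phase \eqn{(-\pi, \pi]} with the R peak at phase 0;
#' the P, Q, R, S and T waves are Gaussian bumps in phase with the given
#' amplitudes (normalized mV), angular positions (rad) and widths (rad).
#' Beat-to-beat RR intervals are lognormal around `60/hr_mean` seconds with
#' coefficient of variation `hr_sd/hr_mean` and AR(1) correlation
#' `hrv_corr`.
#'
#' @param wave_amplitudes named numeric of length 5 (P,Q,R,S,T), normalized mV.
#' @param wave_angles wave centers on the beat cycle, rad; R must sit at 0.
#' @param wave_widths Gaussian widths, rad; all positive.
#' @param hr_mean mean heart rate, beats/min, in `[40, 180]`.
#' @param hr_sd beat-to-beat heart-rate standard deviation, beats/min.
#' @param hrv_corr AR(1) coefficient of the log-RR series, in `[0, 1)`.
#' @return An object of class `ecg_model_params`.
#' @export
ecg_model_params <- function(wave_amplitudes = c(P = 0.12, Q = -0.18, R = 1.2,
                                                 S = -0.25, T = 0.35),
                             wave_angles = c(P = -1.15, Q = -0.22, R = 0,
                                             S = 0.22, T = 1.35),
                             wave_widths = c(P = 0.22, Q = 0.08, R = 0.09,
                                             S = 0.08, T = 0.35),
                             hr_mean = 70, hr_sd = 2.5, hrv_corr = 0.6) {
  p <- list(wave_amplitudes = wave_amplitudes, wave_angles = wave_angles,
            wave_widths = wave_widths, hr_mean = hr_mean, hr_sd = hr_sd,
            hrv_corr = hrv_corr)
  if (!all(vapply(p, function(v) all(is.finite(v)), logical(1))))
    stop_data("ecg_model_params: non-finite parameter")
  if (any(wave_widths <= 0)) stop_data("wave_widths must be positive")
  if (hr_mean < 40 || hr_mean > 180)
    stop_data("hr_mean must lie in [40, 180] bpm")
  if (hr_sd < 0) stop_data("hr_sd must be non-negative")
  if (hrv_corr < 0 || hrv_corr >= 1) stop_data("hrv_corr must lie in [0, 1)")
  if (which.max(abs(wave_amplitudes)) != 3L)
    stop_data("R amplitude must dominate the five waves")
  structure(p, class = "ecg_model_params")
}

#' Generate a synthetic ECG trace with known R-peak times
#'
#' Draws AR(1)-correlated lognormal RR intervals, accumulates a piecewise
#' linear cardiac phase (R peak at phase 0 of each cycle), and evaluates the
#' sum of the five Gaussian waves on the wrapped phase. The first R peak is
#' placed at a seeded uniform offset within the first cycle. The trace is
#' z-normalized (zero mean, unit variance).
#'
#' @param params an [ecg_model_params()] object.
#' @param duration seconds, positive.
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @return A list with `ecg` (length `duration*fs`), `r_peak_times`
#'   (seconds, strictly increasing, within `[0, duration)`), and `t`.
#' @export
generate_ecg <- function(params, duration, fs = 100, seed = 1) {
  if (!inherits(params, "ecg_model_params"))
    params <- do.call(ecg_model_params, params)
  if (!is.finite(duration) || duration <= 0)
    stop_data("duration must be positive")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs

  rr_mean <- 60 / params$hr_mean
  cv <- params$hr_sd / params$hr_mean          # delta-method CV of RR
  rho <- params$hrv_corr
  n_beats <- ceiling(duration / rr_mean) + 4L

  with_seed(child_seed(seed, "ecg-rr"), {
    first_offset <- runif(1, 0, rr_mean)
    if (cv > 0) {
      innov_sd <- cv * sqrt(1 - rho^2)
      z <- numeric(n_beats)
      z[1] <- rnorm(1, 0, cv)
      for (k in seq_len(n_beats - 1L)) z[k + 1] <- rho * z[k] + rnorm(1, 0, innov_sd)
      rr <- rr_mean * exp(z - cv^2 / 2)
    } else {
      rr <- rep(rr_mean, n_beats)
    }
  })

  ## R-peak epochs; beat k occupies [r_k - rr_k/2-ish) in phase terms:
  ## phase is linear between consecutive R peaks, from 0 at r_k to 2*pi at
  ## r_{k+1}. Prepend one peak before t = 0 so that early samples are covered.
  r_times <- first_offset + c(0, cumsum(rr))
  r_times <- c(first_offset - rr[1], r_times)

  ## evaluate the wrapped phase at each sample
  idx <- findInterval(t, r_times)            # beat index for each sample
  idx[idx < 1L] <- 1L
  idx[idx >= length(r_times)] <- length(r_times) - 1L
  seg_start <- r_times[idx]
  seg_len <- r_times[idx + 1L] - r_times[idx]
  phase <- 2 * pi * (t - seg_start) / seg_len   # in [0, 2*pi)
  phase <- ifelse(phase > pi, phase - 2 * pi, phase)  # wrap to (-pi, pi]

  ecg <- numeric(n)
  for (w in seq_along(params$wave_amplitudes)) {
    d <- phase - params$wave_angles[w]
    d <- d - 2 * pi * round(d / (2 * pi))
    ecg <- ecg + params$wave_amplitudes[w] *
      exp(-d^2 / (2 * params$wave_widths[w]^2))
  }

  r_peak_times <- r_times[r_times >= 0 & r_times < duration]
  list(ecg = znorm(ecg), r_peak_times = unname(r_peak_times), t = t)
}
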