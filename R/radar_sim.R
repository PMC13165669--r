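## Physics-based simulator of quadrature continuous-wave radar echoes from
## chest-wall motion: respiration + a damped-oscillation cardiac component,
## phase-modulated onto balanced I/Q channels at the 94 GHz / 3 mm carrier.

#' Radar simulation configuration
#'
#' Constants of the continuous-wave quadrature signal model. The baseband
#' channels are \eqn{I(t) = A\cos[4\pi x(t)/\lambda_0 + \theta(t)]} and
#' \eqn{Q(t) = A\sin[4\pi x(t)/\lambda_0 + \theta(t)]}, where
#' \eqn{\theta(t)} collapses the constant standoff phase plus residual
#' phase noise. Defaults follow the 94 GHz system with its printed 3 mm
#' wavelength (the exact c/f0 is 3.19 mm; override `wavelength_mm` for it).
#'
#' @param carrier_freq_hz carrier frequency, Hz.
#' @param wavelength_mm wavelength, mm; must be within 8% of `c/f0` to allow
#'   the printed nominal 3 mm alongside the exact 3.19 mm.
#' @param standoff_m antenna-to-chest distance, m (enters only via the
#'   constant phase).
#' @param amplitude channel amplitude A (AI = AQ), unitless.
#' @param attenuation amplitude attenuation factor K, unitless.
#' @param constant_phase_rad constant phase offset theta, rad.
#' @param phase_noise_sd residual phase-noise standard deviation, rad.
#' @param awgn_sd additive channel-noise standard deviation, unitless.
#' @param fs sampling rate, Hz (100).
#' @param segment_len samples per segment (1000, i.e. 10 s).
#' @return An object of class `radar_sim_config`.
#' @export
radar_sim_config <- function(carrier_freq_hz = 94e9, wavelength_mm = 3,
                             standoff_m = 1, amplitude = 1, attenuation = 1,
                             constant_phase_rad = 0.7,
                             phase_noise_sd = 0.02, awgn_sd = 0.05,
                             fs = 100, segment_len = 1000) {
  if (wavelength_mm <= 0) stop_config("wavelength must be positive")
  exact <- 299792458 / carrier_freq_hz * 1000
  if (abs(wavelength_mm - exact) / exact > 0.08)
    stop_config("wavelength_mm inconsistent with carrier_freq_hz (c/f0 = ",
                signif(exact, 4), " mm)")
  if (fs * segment_len / fs != segment_len || segment_len != round(fs * segment_len / fs))
    stop_config("segment_len must be an integer number of samples")
  structure(list(carrier_freq_hz = carrier_freq_hz,
                 wavelength_mm = wavelength_mm, standoff_m = standoff_m,
                 amplitude = amplitude, attenuation = attenuation,
                 constant_phase_rad = constant_phase_rad,
                 phase_noise_sd = phase_noise_sd, awgn_sd = awgn_sd,
                 fs = fs, segment_len = segment_len),
            class = "radar_sim_config")
}

## Damped-oscillation kernel for the cardiac chest-wall ring
## (seismocardiogram-like): decaying sinusoid, unit peak amplitude.
cardiac_kernel <- function(fs, ring_freq = 20, decay_s = 0.05,
                           length_s = 0.4) {
  tk <- seq(0, length_s, by = 1 / fs)
  k <- exp(-tk / decay_s) * sin(2 * pi * ring_freq * tk)
  k / max(abs(k))
}

#' Generate chest-wall displacement for one segment
#'
#' Displacement is `respiration + orientation_gain * cardiac`, in mm. The
#' cardiac component is an impulse train at the R-peak times convolved with
#' a decaying 20 Hz sinusoid (50 ms time constant), scaled to peak amplitude
#' `cardiac_amp`. Respiration follows the scenario pattern: eupnea is a
#' sinusoid at `resp_freq`; apnea inserts a randomly placed 3-6 s
#' zero-amplitude epoch; hypoxic breathing scales amplitude by 1.5; rapid
#' shallow breathing scales frequency by 2.5 and amplitude by 0.4.
#'
#' @param r_peak_times R-peak times, seconds, within the segment.
#' @param scenario a [scenario_spec()].
#' @param cardiac_amp peak cardiac displacement, mm, positive.
#' @param duration segment length, seconds.
#' @param fs sampling rate, Hz.
#' @param seed integer seed (apnea epoch placement, respiration phase).
#' @param ring_freq cardiac ring frequency, Hz.
#' @param decay_s cardiac ring decay time constant, s.
#' @return Numeric displacement trace, mm, length `duration*fs`.
#' @export
generate_chest_displacement <- function(r_peak_times, scenario, cardiac_amp,
                                        duration = 10, fs = 100, seed = 1,
                                        ring_freq = 20, decay_s = 0.05) {
  if (cardiac_amp <= 0) stop_data("cardiac_amp must be positive")
  if (length(r_peak_times) &&
      (min(r_peak_times) < 0 || max(r_peak_times) >= duration))
    stop_data("r_peak_times must lie within [0, duration)")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs

  ## cardiac: impulse train at R peaks (nearest sample) * kernel
  impulses <- numeric(n)
  if (length(r_peak_times)) {
    at <- pmin(pmax(round(r_peak_times * fs) + 1, 1), n)
    impulses[at] <- impulses[at] + 1
  }
  k <- cardiac_kernel(fs, ring_freq, decay_s)
  card <- stats::convolve(impulses, rev(k), type = "open")[seq_len(n)]
  card <- cardiac_amp * card

  ## respiration per pattern
  freq <- scenario$resp_freq
  amp <- scenario$resp_amp
  pattern <- scenario$resp_pattern
  if (pattern == "hypoxic") amp <- amp * 1.5
  if (pattern == "rapid_shallow") { freq <- freq * 2.5; amp <- amp * 0.4 }
  resp <- with_seed(child_seed(seed, "resp"), {
    phase0 <- runif(1, 0, 2 * pi)
    r <- amp * sin(2 * pi * freq * t + phase0)
    if (pattern == "apnea" && amp > 0) {
      gap_len <- runif(1, 3, 6)
      gap_start <- runif(1, 0, max(duration - gap_len, 0))
      gate <- !(t >= gap_start & t < gap_start + gap_len)
      r <- r * gate
    }
    r
  })

  resp + scenario$orientation_gain * card
}

#' Modulate a displacement trace onto quadrature radar channels
#'
#' Implements the baseband quadrature model: phase
#' \eqn{4\pi x(t)/\lambda_0 + \theta(t)} with \eqn{\theta(t)} = constant
#' offset + Gaussian phase noise, emitted as `A*cos(.)` (in-phase) and
#' `A*sin(.)` (quadrature), each plus additive Gaussian channel noise.
#'
#' @param x displacement, mm.
#' @param cfg a [radar_sim_config()].
#' @param seed integer seed for the noise draws.
#' @return A list with `i_chan` and `q_chan`.
#' @export
radar_modulate <- function(x, cfg = radar_sim_config(), seed = 1) {
  assert_finite(x, "displacement")
  if (cfg$wavelength_mm <= 0) stop_config("wavelength must be positive")
  n <- length(x)
  phase <- 4 * pi * x / cfg$wavelength_mm + cfg$constant_phase_rad
  with_seed(child_seed(seed, "radar-noise"), {
    if (cfg$phase_noise_sd > 0)
      phase <- phase + rnorm(n, 0, cfg$phase_noise_sd)
    i_chan <- cfg$amplitude * cos(phase)
    q_chan <- cfg$amplitude * sin(phase)
    if (cfg$awgn_sd > 0) {
      i_chan <- i_chan + rnorm(n, 0, cfg$awgn_sd)
      q_chan <- q_chan + rnorm(n, 0, cfg$awgn_sd)
    }
  })
  list(i_chan = i_chan, q_chan = q_chan)
}

#' Generate a subject-structured paired radar/ECG dataset
#'
#' Draws per-subject baseline ECG parameters from stated priors (baseline
#' heart rate uniform on 55-85 bpm, cardiac displacement amplitude uniform
#' on 0.1-0.5 mm, mild morphology jitter), apportions segments over
#' scenarios by largest remainder, and simulates every segment: synthetic
#' ECG, chest displacement, quadrature radar channels. Deterministic under
#' `seed`.
#'
#' @param n_subjects number of subjects, at least 2.
#' @param n_segments total segments across subjects and scenarios.
#' @param scenarios list of [scenario_spec()]; proportions must sum to 1.
#' @param cfg a [radar_sim_config()].
#' @param seed integer seed.
#' @return An object of class `radar_dataset`: list of segments, each with
#'   `subject_id`, `scenario`, `t`, `i_chan`, `q_chan`, `x`, `ecg`,
#'   `r_peak_times`, `fs`.
#' @export
generate_dataset <- function(n_subjects, n_segments,
                             scenarios = default_scenarios(),
                             cfg = radar_sim_config(), seed = 1) {
  if (n_subjects < 2) stop_config("need at least 2 subjects")
  check_proportions(scenarios)
  props <- vapply(scenarios, `[[`, numeric(1), "proportion")
  counts <- apportion_counts(n_segments, props)
  duration <- cfg$segment_len / cfg$fs

  subject_ids <- sprintf("S%02d", seq_len(n_subjects))
  subjects <- lapply(seq_len(n_subjects), function(s) {
    with_seed(child_seed(seed, paste0("subject-", s)), {
      base <- ecg_model_params()
      amp_jit <- runif(5, 0.9, 1.1)
      width_jit <- runif(5, 0.9, 1.1)
      list(hr_mean = runif(1, 55, 85),
           cardiac_amp = runif(1, 0.1, 0.5),
           wave_amplitudes = base$wave_amplitudes * amp_jit,
           wave_widths = base$wave_widths * width_jit,
           wave_angles = base$wave_angles)
    })
  })

  ## round-robin scenario segments over subjects for balanced coverage
  segments <- vector("list", n_segments)
  seg_i <- 0L
  for (sc in seq_along(scenarios)) {
    scen <- scenarios[[sc]]
    for (j in seq_len(counts[sc])) {
      seg_i <- seg_i + 1L
      subj <- ((seg_i - 1L) %% n_subjects) + 1L
      sp <- subjects[[subj]]
      seg_seed <- child_seed(seed, paste0("seg-", sc, "-", j, "-", subj))
      params <- ecg_model_params(
        wave_amplitudes = sp$wave_amplitudes,
        wave_angles = sp$wave_angles,
        wave_widths = sp$wave_widths,
        hr_mean = min(sp$hr_mean + scen$hr_shift, 180),
        hr_sd = 2.5, hrv_corr = 0.6)
      e <- generate_ecg(params, duration, cfg$fs, seed = seg_seed)
      x <- generate_chest_displacement(e$r_peak_times, scen, sp$cardiac_amp,
                                       duration, cfg$fs, seed = seg_seed)
      iq <- radar_modulate(x, cfg, seed = seg_seed)
      segments[[seg_i]] <- list(
        subject_id = subject_ids[subj], scenario = scen$name,
        t = e$t, i_chan = iq$i_chan, q_chan = iq$q_chan,
        x = x, ecg = e$ecg, r_peak_times = e$r_peak_times, fs = cfg$fs)
    }
  }

  ## stable ordering by (subject, then original index)
  ord <- order(vapply(segments, `[[`, character(1), "subject_id"),
               seq_along(segments))
  structure(list(segments = segments[ord], cfg = cfg, seed = seed,
                 scenario_counts = setNames(
                   counts, vapply(scenarios, `[[`, character(1), "name"))),
            class = "radar_dataset")
}

#' @export
print.radar_dataset <- function(x, ...) {
  cat("radar_dataset:", length(x$segments), "segments,",
      length(unique(vapply(x$segments, `[[`, character(1), "subject_id"))),
      "subjects\n")
  print(x$scenario_counts)
  invisible(x)
}
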