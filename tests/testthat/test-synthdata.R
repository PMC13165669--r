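test_that("zero-variance heart rate gives exactly periodic R peaks", {
  e <- generate_ecg(ecg_model_params(hr_mean = 60, hr_sd = 0), 10, seed = 3)
  expect_true(length(e$r_peak_times) %in% c(10L, 11L))
  expect_equal(diff(e$r_peak_times), rep(1, length(e$r_peak_times) - 1),
               tolerance = 1e-12)
  expect_length(e$ecg, 1000)
  expect_equal(mean(e$ecg), 0, tolerance = 1e-12)
  expect_equal(sd(e$ecg), 1, tolerance = 1e-12)
})

test_that("ECG generation is deterministic under a seed", {
  a <- generate_ecg(ecg_model_params(), 10, seed = 7)
  b <- generate_ecg(ecg_model_params(), 10, seed = 7)
  expect_identical(a, b)
  c <- generate_ecg(ecg_model_params(), 10, seed = 8)
  expect_false(identical(a$ecg, c$ecg))
})

test_that("mean RR interval tracks the configured heart rate", {
  e <- generate_ecg(ecg_model_params(hr_mean = 75, hr_sd = 3), 60, seed = 1)
  rr <- diff(e$r_peak_times)   # brute-force tally from the peak list
  ## 3-sigma bound on the mean, inflated for the AR(1) correlation
  ## (rho = 0.6) of consecutive RR intervals
  infl <- sqrt((1 + 0.6) / (1 - 0.6))
  expect_lt(abs(mean(rr) - 0.8), 3 * infl * sd(rr) / sqrt(length(rr)))
  expect_true(all(e$r_peak_times >= 0 & e$r_peak_times < 60))
  expect_true(all(diff(e$r_peak_times) > 0))
})

test_that("invalid ECG parameters are rejected", {
  expect_error(ecg_model_params(hr_mean = 30), class = "radarecg_data_error")
  expect_error(ecg_model_params(hrv_corr = 1), class = "radarecg_data_error")
  expect_error(ecg_model_params(wave_widths = c(0.2, -0.1, 0.1, 0.1, 0.3)),
               class = "radarecg_data_error")
  expect_error(generate_ecg(ecg_model_params(), duration = -1),
               class = "radarecg_data_error")
})

test_that("a single impulse produces the cardiac kernel at the R time", {
  scen <- scenario_spec("test", 1.0, 0.25, 0, "eupnea")
  x <- generate_chest_displacement(5, scen, cardiac_amp = 0.3, seed = 1)
  expect_equal(max(abs(x)), 0.3, tolerance = 1e-9)
  expect_gt(which.max(abs(x)) / 100, 5)     # kernel rings after the peak
  expect_lt(which.max(abs(x)) / 100, 5.1)
  expect_equal(x[1:500], rep(0, 500))       # silent before the beat
})

test_that("apnea inserts a contiguous respiration-free epoch of >= 3 s", {
  scen <- scenario_spec("test", 1.0, 0.25, 2, "apnea")
  ## cardiac component suppressed via empty peak list: pure respiration
  x <- generate_chest_displacement(numeric(0), scen, cardiac_amp = 0.1,
                                   seed = 4)
  runs <- rle(abs(x) < 1e-12)
  expect_gte(max(runs$lengths[runs$values]), 300)
})

test_that("eupnea respiration peaks at the configured frequency", {
  scen <- scenario_spec("test", 1.0, 0.25, 4, "eupnea")
  ## 20 s so the periodogram grid (0.05 Hz) contains 0.25 Hz exactly
  x <- generate_chest_displacement(numeric(0), scen, cardiac_amp = 0.1,
                                   duration = 20, seed = 2)
  ## oracle: direct periodogram argmax
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))[2:(n / 2)]
  freqs <- (1:(n / 2 - 1)) * 100 / n
  expect_equal(freqs[which.max(sp)], 0.25, tolerance = 1e-9)
})

test_that("breathing patterns rescale frequency and amplitude as specified", {
  base <- scenario_spec("eu", 1.0, 0.2, 2, "eupnea")
  rsb <- scenario_spec("rsb", 1.0, 0.2, 2, "rapid_shallow")
  hyp <- scenario_spec("hy", 1.0, 0.2, 2, "hypoxic")
  xe <- generate_chest_displacement(numeric(0), base, 0.1, seed = 5)
  xr <- generate_chest_displacement(numeric(0), rsb, 0.1, seed = 5)
  xh <- generate_chest_displacement(numeric(0), hyp, 0.1, seed = 5)
  n <- length(xe)
  freqs <- (1:(n / 2 - 1)) * 100 / n
  peak_f <- function(x) freqs[which.max(Mod(fft(x - mean(x)))[2:(n / 2)])]
  expect_equal(peak_f(xr) / peak_f(xe), 2.5, tolerance = 0.25)
  expect_equal(max(abs(xr)) / max(abs(xe)), 0.4, tolerance = 0.02)
  expect_equal(max(abs(xh)) / max(abs(xe)), 1.5, tolerance = 0.02)
  expect_error(scenario_spec("bad", 1, 0.2, 2, "cheyne_stokes"),
               class = "radarecg_config_error")
})

test_that("quadrature modulation follows the baseband signal model", {
  cfg <- radar_sim_config(phase_noise_sd = 0, awgn_sd = 0,
                          constant_phase_rad = 0)
  iq <- radar_modulate(rep(0, 100), cfg, seed = 1)
  expect_equal(iq$i_chan, rep(cfg$amplitude, 100))
  expect_equal(iq$q_chan, rep(0, 100))

  t <- (0:999) / 100
  x <- 0.2 * sin(2 * pi * 1.2 * t)
  iq <- radar_modulate(x, cfg, seed = 1)
  ## amplitude constancy (Pythagorean identity)
  expect_lt(max(abs(iq$i_chan^2 + iq$q_chan^2 - cfg$amplitude^2)), 1e-10)
  ## peak phase excursion = direct evaluation of 4*pi*x/lambda, which
  ## approaches the closed form 4*pi*0.2/3 = 0.8378 on the sample grid
  phase <- atan2(iq$q_chan, iq$i_chan)
  expect_equal(max(phase), max(4 * pi * x / 3), tolerance = 1e-9)
  expect_equal(max(4 * pi * x / 3), 4 * pi * 0.2 / 3, tolerance = 1e-3)
})

test_that("wavelength must be consistent with the carrier", {
  expect_error(radar_sim_config(wavelength_mm = 5),
               class = "radarecg_config_error")
  ## the printed 3 mm and the exact c/f0 = 3.19 mm are both accepted
  expect_silent(radar_sim_config(wavelength_mm = 3))
  expect_silent(radar_sim_config(wavelength_mm = 3.189))
})

test_that("largest-remainder apportionment reproduces the study's counts", {
  counts <- c(2816, 1199, 1077, 968, 571, 458, 432)
  props <- vapply(default_scenarios(), `[[`, numeric(1), "proportion")
  expect_equal(sum(props), 1, tolerance = 1e-12)
  expect_identical(apportion_counts(7521, props), as.integer(counts))
  expect_identical(sum(apportion_counts(7521, props)) * 1000L, 7521000L)
  ## apportioned counts always sum to n
  for (n in c(1, 7, 100, 7521)) {
    expect_identical(sum(apportion_counts(n, props)), as.integer(n))
  }
  expect_error(apportion_counts(10, c(0.5, 0.4)),
               class = "radarecg_config_error")
})

test_that("dataset generation is balanced, labeled and reproducible", {
  scen <- default_scenarios()
  for (i in seq_along(scen)) scen[[i]]$proportion <- 1 / 7
  ds1 <- generate_dataset(2, 14, scen, seed = 5)
  expect_identical(unname(ds1$scenario_counts), rep(2L, 7))
  expect_length(ds1$segments, 14)
  subj <- vapply(ds1$segments, `[[`, character(1), "subject_id")
  expect_setequal(unique(subj), c("S01", "S02"))
  ## regeneration is bit-identical, including a written store
  ds2 <- generate_dataset(2, 14, scen, seed = 5)
  expect_identical(ds1, ds2)
  d1 <- file.path(tempdir(), "store_a"); d2 <- file.path(tempdir(), "store_b")
  write_segment_store(ds1, d1); write_segment_store(ds2, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("noiseless segments satisfy the envelope identity", {
  cfg <- radar_sim_config(phase_noise_sd = 0, awgn_sd = 0)
  ds <- generate_dataset(2, 4, cfg = cfg, seed = 9)
  for (seg in ds$segments) {
    expect_lt(max(abs(seg$i_chan^2 + seg$q_chan^2 - cfg$amplitude^2)), 1e-10)
  }
})
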