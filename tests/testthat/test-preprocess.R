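test_that("MODWT matches a direct-sum reference implementation", {
  set.seed(1)
  x <- rnorm(64)
  filt <- oracle_db4()
  ref <- naive_modwt(x, filt$g, filt$h, 3)
  dec <- modwt(x, "db4", 3)
  for (j in 1:3) expect_equal(dec$W[[j]], ref$W[[j]], tolerance = 1e-10)
  expect_equal(dec$V, ref$V, tolerance = 1e-10)
})

test_that("MODWT inverse and additive reconstruction are exact", {
  set.seed(2)
  for (n in c(512, 1000, 1024)) {
    x <- rnorm(n)
    dec <- modwt(x, "db4", 6)
    expect_lt(max(abs(imodwt(dec) - x)), 1e-8)
    mra <- modwt_mra(x, "db4", 6)
    expect_lt(max(abs(Reduce(`+`, mra$D) + mra$S - x)), 1e-8)
  }
  expect_error(modwt(rnorm(16), "db4", 7), class = "radarecg_data_error")
})

test_that("level bands follow the dyadic octave layout", {
  mra <- modwt_mra(rnorm(256), "db4", 4, fs = 100)
  expect_equal(mra$level_band[, "high_hz"], 100 / 2^(1:4))
  expect_equal(mra$level_band[, "low_hz"], 100 / 2^(2:5))
})

test_that("respiratory suppression keeps cardiac tones and rejects breathing", {
  t <- (0:999) / 100
  cardiac <- sin(2 * pi * 1.2 * t)
  resp <- sin(2 * pi * 0.25 * t)
  s1 <- modwt_suppress_respiration(cardiac)
  ## oracle: energy ratio by direct periodogram
  expect_gte(sum(s1$x_cardiac^2) / sum(cardiac^2), 0.95)
  ## the level whose octave band contains 1.2 Hz must be selected
  band_holds <- which(100 / 2^(s1$selected_levels + 1) <= 1.2 &
                        100 / 2^s1$selected_levels >= 1.2)
  expect_gt(length(band_holds), 0)
  s2 <- modwt_suppress_respiration(resp)
  amp_in <- 2 * Mod(fft(resp))[which.min(abs((0:999) * 0.1 - 0.25))] / 1000
  amp_out <- 2 * Mod(fft(s2$x_cardiac))[which.min(abs((0:999) * 0.1 - 0.25))] / 1000
  expect_gte(20 * log10(amp_in / max(amp_out, 1e-300)), 20)
  s0 <- modwt_suppress_respiration(rep(0, 1000))
  expect_equal(s0$x_cardiac, rep(0, 1000))
})

test_that("suppression is linear for a fixed level selection", {
  set.seed(3)
  x <- sin(2 * pi * 1.2 * (0:999) / 100) + 0.1 * rnorm(1000)
  a <- modwt_suppress_respiration(x)
  b <- modwt_suppress_respiration(3 * x)
  expect_identical(a$selected_levels, b$selected_levels)
  expect_equal(b$x_cardiac, 3 * a$x_cardiac, tolerance = 1e-10)
})

test_that("adaptive Kalman filter tracks a constant input", {
  x <- rep(2.5, 400)
  xf <- akf_filter(x, akf_config(r0 = 1e-4))
  expect_lt(max(abs(tail(xf, 100) - 2.5)), 1e-6)
})

test_that("adaptive Kalman filter denoises a cardiac-band sinusoid", {
  set.seed(1)
  t <- (0:999) / 100
  s <- 0.3 * sin(2 * pi * 1.2 * t)
  x <- s + rnorm(1000, 0, 0.1)
  xf <- akf_filter(x, akf_config())
  expect_lt(sqrt(mean((xf - s)^2)), sqrt(mean((x - s)^2)))
})

test_that("forgetting = 1 reduces to the fixed-covariance Kalman filter", {
  set.seed(4)
  x <- cumsum(rnorm(300, 0, 0.05)) + rnorm(300, 0, 0.1)
  cfg <- akf_config(q0 = 2e-3, r0 = 5e-3, forgetting = 1,
                    cardiac_freq_weight = 0)
  expect_equal(akf_filter(x, cfg), ref_kalman(x, 2e-3, 5e-3),
               tolerance = 1e-12)
  expect_error(akf_filter(c(1, NA, 2)), class = "radarecg_data_error")
  expect_error(akf_config(forgetting = 0), class = "radarecg_config_error")
})

test_that("polynomial baseline removal annihilates its own model", {
  t <- seq(-1, 1, length.out = 500)
  poly5 <- 3 - 2 * t + t^2 + 0.5 * t^3 - t^4 + 2 * t^5
  out <- ecg_remove_baseline(poly5)
  expect_lt(max(abs(out)), 1e-6 * max(abs(poly5)))
  expect_equal(ecg_remove_baseline(rep(3, 100)), rep(0, 100),
               tolerance = 1e-10)
})

test_that("baseline removal restores a drifting ECG", {
  e <- generate_ecg(ecg_model_params(), 10, seed = 2)
  drift <- 0.5 * ((0:999) / 100)^2
  out <- ecg_remove_baseline(e$ecg + drift)
  expect_gt(cor(out, e$ecg), 0.99)
})

test_that("soft thresholding shrinks coefficients as defined", {
  st <- radarecg:::soft_threshold
  expect_equal(st(2.0, 0.5), 1.5)
  expect_equal(st(-0.3, 0.5), 0)
  expect_equal(st(-2.0, 0.5), -1.5)
})

test_that("MAD noise estimate recovers the generating sigma", {
  set.seed(5)
  x <- rnorm(1000, 0, 0.1)
  den <- ecg_wavelet_denoise(x)
  expect_gte(attr(den, "sigma"), 0.08)
  expect_lte(attr(den, "sigma"), 0.12)
})

test_that("wavelet denoising is near-identity on clean signal and a contraction", {
  e <- generate_ecg(ecg_model_params(), 10, seed = 6)
  den <- ecg_wavelet_denoise(e$ecg)
  expect_gt(cor(as.numeric(den), e$ecg), 0.999)
  set.seed(7)
  for (rep in 1:3) {
    x <- rnorm(500)
    expect_lte(sqrt(sum(ecg_wavelet_denoise(x)^2)), sqrt(sum(x^2)) + 1e-9)
  }
})

test_that("preprocess_dataset attaches cardiac displacement and clean ECG", {
  cfg <- radar_sim_config(phase_noise_sd = 0.01, awgn_sd = 0.02)
  ds <- preprocess_dataset(demodulate_dataset(
    generate_dataset(2, 4, cfg = cfg, seed = 3)))
  for (seg in ds$segments) {
    expect_length(seg$x_card, 1000)
    expect_length(seg$ecg_clean, 1000)
    expect_true(all(is.finite(seg$x_card)))
    ## cleaned ECG stays faithful to the generated ECG
    expect_gt(cor(seg$ecg_clean, seg$ecg), 0.98)
  }
})
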