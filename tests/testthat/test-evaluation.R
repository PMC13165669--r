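test_that("metric kernels agree with straight-from-formula references", {
  set.seed(1)
  for (rep in 1:5) {
    a <- rnorm(200); b <- rnorm(200)
    ref_pcc <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pcc(a, b), ref_pcc, tolerance = 1e-12)
    expect_equal(mae(a, b), mean(abs(a - b)), tolerance = 1e-12)
    expect_equal(rmse(a, b), sqrt(mean((a - b)^2)), tolerance = 1e-12)
    expect_gte(rmse(a, b), mae(a, b))     # power-mean inequality
  }
})

test_that("pcc handles identity, inversion, affine maps and degeneracy", {
  y <- rnorm(100)
  expect_equal(pcc(y, y), 1)
  expect_equal(pcc(-y, y), -1)
  expect_equal(pcc(2.5 * y + 3, y), 1, tolerance = 1e-12)
  expect_error(pcc(rep(1, 100), y), class = "radarecg_data_error")
})

test_that("mae matches the hand-computed example", {
  expect_equal(mae(c(1, 2, 3), c(1, 1, 1)), 1.0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
})

test_that("R peaks of clean synthetic ECG are found within 10 ms", {
  for (hr in c(62, 75, 88)) {
    e <- generate_ecg(ecg_model_params(hr_mean = hr, hr_sd = 2), 10,
                      seed = hr)
    ann <- detect_waves(e$ecg, 100)
    ## every true R peak matched by a detection within 10 ms
    expect_gte(length(ann$r_times), length(e$r_peak_times) - 1)
    for (rt in e$r_peak_times) {
      expect_lte(min(abs(ann$r_times - rt)), 0.010 + 1e-9)
    }
    ## per-beat ordering q < r < s, and each t follows its r by 0.1-0.4 s
    expect_true(all(ann$q_times < ann$r_times))
    expect_true(all(ann$r_times < ann$s_times))
    for (tt in ann$t_times) {
      r_before <- max(ann$r_times[ann$r_times < tt])
      expect_gt(tt - r_before, 0.09)
      expect_lt(tt - r_before, 0.41)
    }
  }
})

test_that("flat traces yield an empty annotation with a warning", {
  expect_warning(ann <- detect_waves(rep(0, 1000), 100), "no beats")
  expect_length(ann$r_times, 0)
  expect_error(detect_waves(rep(0, 100), 100), class = "radarecg_data_error")
})

test_that("a pluggable detector is honoured", {
  fake <- function(ecg, fs) structure(list(q_times = 1, r_times = 2,
                                           s_times = 3, t_times = 4),
                                      class = "wave_annotation")
  ann <- detect_waves(rnorm(1000), 100, detector = fake)
  expect_equal(ann$r_times, 2)
})

test_that("localization errors match the exhaustive matcher", {
  mk <- function(r) structure(list(q_times = r, r_times = r, s_times = r,
                                   t_times = r), class = "wave_annotation")
  ## identical annotations: zero error, no misses
  le <- localization_errors(mk(c(1, 2, 3)), mk(c(1, 2, 3)))
  expect_equal(le$r$errors, c(0, 0, 0))
  expect_identical(le$r$misses, 0L)
  ## uniform shift
  le2 <- localization_errors(mk(c(1.02, 2.02, 3.02)), mk(c(1, 2, 3)))
  expect_equal(le2$r$errors, rep(0.02, 3), tolerance = 1e-12)
  ## the worked example, against exhaustive pairing
  hat <- c(1.004, 2.5, 3.01); ref <- c(1, 2, 3)
  le3 <- localization_errors(mk(hat), mk(ref), match_window = 0.15)
  oracle <- brute_force_match(hat, ref, 0.15)
  expect_equal(sort(le3$r$errors), oracle$errors, tolerance = 1e-12)
  expect_identical(le3$r$misses, as.integer(oracle$misses))
  expect_equal(oracle$errors, c(0.004, 0.01), tolerance = 1e-12)
  expect_identical(oracle$misses, 1L)
  ## randomized agreement with the exhaustive matcher
  set.seed(2)
  for (rep in 1:10) {
    ref <- sort(runif(4, 0, 10))
    hat <- sort(c(ref[1:3] + rnorm(3, 0, 0.05), runif(1, 0, 10)))
    a <- localization_errors(mk(hat), mk(ref), 0.15)$r
    b <- brute_force_match(hat, ref, 0.15)
    expect_identical(length(a$errors), length(b$errors))
    expect_identical(a$misses, as.integer(b$misses))
  }
})

test_that("summaries follow the linear-interpolation percentile convention", {
  errs <- (1:10) * 0.001
  per <- lapply(errs, function(e) list(
    pcc = 0.9, rmse = 0.1, mae = 0.05, scenario = "all",
    loc = list(q = list(errors = e, misses = 0L),
               r = list(errors = e, misses = 0L),
               s = list(errors = e, misses = 0L),
               t = list(errors = e, misses = 0L))))
  rep <- summarize_eval(per)
  r_row <- rep$localization[rep$localization$wave == "R", ]
  expect_equal(r_row$median, 0.0055)
  expect_equal(r_row$p90, 0.0091)
  ## CDF is non-decreasing from 1/n to 1
  expect_equal(tail(rep$cdf$pcc$cum_fraction, 1), 1.0)
  expect_true(all(diff(rep$cdf$rmse$cum_fraction) >= 0))
  expect_true(all(diff(rep$cdf$rmse$value) >= 0))
})

test_that("single-segment aggregates equal the segment metrics", {
  set.seed(3)
  y <- as.numeric(generate_ecg(ecg_model_params(), 10, seed = 4)$ecg)
  yh <- y + rnorm(1000, 0, 0.1)
  rep <- evaluate_reconstructions(matrix(yh, 1), matrix(y, 1))
  expect_equal(rep$overall$pcc, pcc(yh, y))
  expect_equal(rep$overall$rmse, rmse(yh, y))
  expect_equal(rep$overall$mae, mae(yh, y))
  expect_identical(rep$overall$n, 1L)
})

test_that("degenerate segments are excluded from PCC and counted", {
  y <- as.numeric(generate_ecg(ecg_model_params(), 10, seed = 5)$ecg)
  Yhat <- rbind(y, 0)          # second reconstruction is flat
  Y <- rbind(y, y)
  rep <- suppressWarnings(
    evaluate_reconstructions(Yhat, Y, scenarios = c("a", "b")))
  expect_identical(rep$overall$n_degenerate, 1L)
  expect_equal(rep$overall$pcc, 1)
  expect_identical(nrow(rep$per_scenario), 2L)
})
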