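## Morphological metrics, Q/R/S/T wave localization and report assembly.

#' Pearson correlation coefficient
#'
#' @param y_hat,y equal-length numeric vectors with nonzero variance.
#' @return Scalar in `[-1, 1]`.
#' @export
pcc <- function(y_hat, y) {
  if (length(y_hat) != length(y)) stop_data("pcc: length mismatch")
  if (sd(y_hat) == 0 || sd(y) == 0)
    stop_data("pcc undefined: zero variance")
  dh <- y_hat - mean(y_hat)
  dy <- y - mean(y)
  sum(dh * dy) / sqrt(sum(dh^2) * sum(dy^2))
}

#' Mean absolute error
#' @param y_hat,y equal-length numeric vectors.
#' @return Scalar, non-negative.
#' @export
mae <- function(y_hat, y) {
  if (length(y_hat) != length(y)) stop_data("mae: length mismatch")
  mean(abs(y_hat - y))
}

#' Root mean squared error
#' @param y_hat,y equal-length numeric vectors.
#' @return Scalar, non-negative.
#' @export
rmse <- function(y_hat, y) {
  if (length(y_hat) != length(y)) stop_data("rmse: length mismatch")
  sqrt(mean((y_hat - y)^2))
}

#' Detect Q, R, S and T wave peaks
#'
#' Built-in detector in the moving-window-integration tradition: R peaks
#' from a 5-20 Hz bandpass, squared derivative, 150 ms moving-window
#' integration and adaptive-threshold peak picking with a 250 ms
#' refractory period, refined to the local extremum of the raw trace
#' within +/- 40 ms; Q and S as local minima within 60 ms before/after
#' each R; T as the local maximum 100-400 ms after R. A custom `detector`
#' function (signature `(ecg, fs)`) can be substituted, e.g. an adapter to
#' an external ECG toolkit.
#'
#' @param ecg numeric trace, at least 2 s.
#' @param fs sampling rate, Hz.
#' @param detector optional replacement detector returning a
#'   `wave_annotation`.
#' @return An object of class `wave_annotation`: lists `q_times`,
#'   `r_times`, `s_times`, `t_times` in seconds. Empty (with a warning)
#'   when no beats are found.
#' @export
detect_waves <- function(ecg, fs = 100, detector = NULL) {
  if (!is.null(detector)) return(detector(ecg, fs))
  n <- length(ecg)
  if (n < 2 * fs) stop_data("need at least 2 s of signal")
  empty <- structure(list(q_times = numeric(0), r_times = numeric(0),
                          s_times = numeric(0), t_times = numeric(0)),
                     class = "wave_annotation")
  if (sd(ecg) == 0) {
    warning("no beats found: flat trace")
    return(empty)
  }
  bp <- signal::butter(2, c(5, 20) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, ecg)
  der <- c(diff(xf), 0)
  sq <- der^2
  w <- max(1L, round(0.15 * fs))
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  thr <- 0.25 * max(mwi)
  refractory <- round(0.25 * fs)
  cand <- which(mwi > thr &
                  mwi >= c(-Inf, head(mwi, -1)) &
                  mwi > c(tail(mwi, -1), Inf))
  r_idx <- integer(0)
  last <- -Inf
  for (ci in cand) {
    if (ci - last > refractory) {
      r_idx <- c(r_idx, ci)
      last <- ci
    } else if (mwi[ci] > mwi[last]) {
      r_idx[length(r_idx)] <- ci
      last <- ci
    }
  }
  if (!length(r_idx)) {
    warning("no beats found")
    return(empty)
  }
  ## refine R to raw-trace extremum within +/- 40 ms
  half <- as.integer(round(0.04 * fs))
  r_idx <- vapply(r_idx, function(ri) {
    lo <- max(1L, ri - half); hi <- min(n, ri + half)
    lo - 1L + which.max(ecg[lo:hi])
  }, numeric(1))
  r_idx <- as.integer(sort(unique(r_idx)))

  q_win <- round(0.06 * fs)
  t_lo <- round(0.10 * fs); t_hi <- round(0.40 * fs)
  q_idx <- s_idx <- t_idx <- rep(NA_integer_, length(r_idx))
  for (i in seq_along(r_idx)) {
    ri <- r_idx[i]
    lo <- max(1, ri - q_win)
    if (lo < ri) q_idx[i] <- lo - 1L + which.min(ecg[lo:(ri - 1)])
    hi <- min(n, ri + q_win)
    if (hi > ri) s_idx[i] <- ri + which.min(ecg[(ri + 1):hi])
    tl <- min(n, ri + t_lo); th <- min(n, ri + t_hi)
    if (th > tl) t_idx[i] <- tl - 1L + which.max(ecg[tl:th])
  }
  ## beats lacking Q or S (possible only at the trace edges) are dropped
  ## jointly; a missing T (window truncated at the end) drops only the T
  keep <- !is.na(q_idx) & !is.na(s_idx)
  structure(list(q_times = (q_idx[keep] - 1) / fs,
                 r_times = (r_idx[keep] - 1) / fs,
                 s_times = (s_idx[keep] - 1) / fs,
                 t_times = (t_idx[keep & !is.na(t_idx)] - 1) / fs),
            class = "wave_annotation")
}

#' Wave localization errors between two annotations
#'
#' Greedy nearest-neighbour matching of reconstructed peaks to reference
#' peaks within `+/- match_window`; each reconstructed peak matches at
#' most one reference peak. Unmatched reference peaks are counted as
#' misses and excluded from the error lists.
#'
#' @param ann_hat annotation of the reconstructed trace.
#' @param ann_ref annotation of the ground-truth trace.
#' @param match_window seconds, default 0.15.
#' @return A list per wave (`q`, `r`, `s`, `t`) with `errors` (absolute
#'   seconds) and `misses` (count).
#' @export
localization_errors <- function(ann_hat, ann_ref, match_window = 0.15) {
  match_wave <- function(hat, ref) {
    if (!length(ref)) return(list(errors = numeric(0), misses = 0L))
    avail <- rep(TRUE, length(hat))
    errors <- numeric(0)
    misses <- 0L
    ## process reference peaks in order of best available match
    pairs <- expand.grid(r = seq_along(ref), h = seq_along(hat))
    if (nrow(pairs)) {
      pairs$d <- abs(ref[pairs$r] - hat[pairs$h])
      pairs <- pairs[pairs$d <= match_window, , drop = FALSE]
      pairs <- pairs[order(pairs$d), , drop = FALSE]
      used_r <- rep(FALSE, length(ref))
      for (k in seq_len(nrow(pairs))) {
        r <- pairs$r[k]; h <- pairs$h[k]
        if (!used_r[r] && avail[h]) {
          used_r[r] <- TRUE
          avail[h] <- FALSE
          errors <- c(errors, pairs$d[k])
        }
      }
      misses <- sum(!used_r)
    } else {
      misses <- length(ref)
    }
    list(errors = errors, misses = misses)
  }
  list(q = match_wave(ann_hat$q_times, ann_ref$q_times),
       r = match_wave(ann_hat$r_times, ann_ref$r_times),
       s = match_wave(ann_hat$s_times, ann_ref$s_times),
       t = match_wave(ann_hat$t_times, ann_ref$t_times))
}

#' Evaluate reconstructions against ground truth
#'
#' Computes per-segment PCC, RMSE and MAE plus Q/R/S/T localization
#' errors, then aggregates with [summarize_eval()]. Segments with zero
#' variance in either trace are excluded from the correlation aggregates
#' and counted.
#'
#' @param Yhat,Y batch x L matrices (reconstructed, ground truth).
#' @param scenarios optional character vector of per-segment scenario
#'   labels.
#' @param fs sampling rate, Hz.
#' @param match_window peak-matching window, seconds.
#' @return An `eval_report`, see [summarize_eval()].
#' @export
evaluate_reconstructions <- function(Yhat, Y, scenarios = NULL, fs = 100,
                                     match_window = 0.15) {
  B <- nrow(Y)
  per <- lapply(seq_len(B), function(i) {
    yh <- Yhat[i, ]; yt <- Y[i, ]
    degenerate <- sd(yh) == 0 || sd(yt) == 0
    loc <- localization_errors(detect_waves(yh, fs), detect_waves(yt, fs),
                               match_window)
    list(pcc = if (degenerate) NA_real_ else pcc(yh, yt),
         rmse = rmse(yh, yt), mae = mae(yh, yt),
         scenario = if (is.null(scenarios)) "all" else scenarios[i],
         loc = loc)
  })
  summarize_eval(per)
}

#' Aggregate per-segment evaluation results
#'
#' Median and 90th percentile use linear interpolation between closest
#' ranks; CDF tables pair sorted values with cumulative fractions
#' `rank/n`.
#'
#' @param per_segment list of per-segment results (fields `pcc`, `rmse`,
#'   `mae`, `scenario`, `loc`).
#' @return An object of class `eval_report`: `overall` (mean PCC/RMSE/MAE,
#'   `n`, `n_degenerate`), `per_scenario` data frame, `localization`
#'   data frame (wave, median, p90, n, misses), `cdf` (named list of
#'   data frames), `per_segment`.
#' @export
summarize_eval <- function(per_segment) {
  stopifnot(length(per_segment) >= 1)
  pccs <- vapply(per_segment, `[[`, numeric(1), "pcc")
  rmses <- vapply(per_segment, `[[`, numeric(1), "rmse")
  maes <- vapply(per_segment, `[[`, numeric(1), "mae")
  scen <- vapply(per_segment, `[[`, character(1), "scenario")
  overall <- list(pcc = mean(pccs, na.rm = TRUE), rmse = mean(rmses),
                  mae = mean(maes), n = length(per_segment),
                  n_degenerate = sum(is.na(pccs)))
  per_scenario <- do.call(rbind, lapply(unique(scen), function(s) {
    k <- scen == s
    data.frame(scenario = s, pcc = mean(pccs[k], na.rm = TRUE),
               rmse = mean(rmses[k]), mae = mean(maes[k]), n = sum(k))
  }))
  waves <- c("q", "r", "s", "t")
  localization <- do.call(rbind, lapply(waves, function(w) {
    errs <- unlist(lapply(per_segment, function(p) p$loc[[w]]$errors))
    miss <- sum(vapply(per_segment, function(p) p$loc[[w]]$misses, 1L))
    data.frame(wave = toupper(w),
               median = if (length(errs)) unname(quantile(errs, 0.5, type = 7)) else NA_real_,
               p90 = if (length(errs)) unname(quantile(errs, 0.9, type = 7)) else NA_real_,
               n = length(errs), misses = miss)
  }))
  cdf_of <- function(v) {
    v <- sort(v[is.finite(v)])
    data.frame(value = v, cum_fraction = seq_along(v) / length(v))
  }
  structure(list(overall = overall, per_scenario = per_scenario,
                 localization = localization,
                 cdf = list(pcc = cdf_of(pccs), rmse = cdf_of(rmses)),
                 per_segment = per_segment),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: n = %d (degenerate excluded: %d)\n",
              x$overall$n, x$overall$n_degenerate))
  cat(sprintf("  PCC %.4f  RMSE %.4f  MAE %.4f\n", x$overall$pcc,
              x$overall$rmse, x$overall$mae))
  print(x$localization, row.names = FALSE)
  invisible(x)
}
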