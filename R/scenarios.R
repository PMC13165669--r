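## The seven posture / breathing scenarios and their dataset proportions.

#' Scenario specification
#'
#' One posture/orientation/breathing scenario. `orientation_gain` scales the
#' cardiac displacement amplitude seen by the radar (chest-facing > lateral >
#' back). `hr_shift` is added to the subject's baseline heart rate to emulate
#' the sympathetic response to hypoxia. `proportion` is the fraction of the
#' dataset generated under this scenario.
#'
#' @param name scenario label.
#' @param orientation_gain unitless, in `(0, 1]`.
#' @param resp_freq respiration rate, Hz.
#' @param resp_amp respiration displacement amplitude, mm, non-negative.
#' @param resp_pattern one of `"eupnea"`, `"apnea"`, `"hypoxic"`,
#'   `"rapid_shallow"`.
#' @param hr_shift beats/min added to the subject baseline heart rate.
#' @param proportion fraction of the dataset, in `[0, 1]`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, orientation_gain, resp_freq, resp_amp,
                          resp_pattern, hr_shift = 0, proportion = 1) {
  patterns <- c("eupnea", "apnea", "hypoxic", "rapid_shallow")
  if (!resp_pattern %in% patterns)
    stop_config("unknown resp_pattern '", resp_pattern, "'")
  if (resp_amp < 0) stop_config("resp_amp must be non-negative")
  if (orientation_gain <= 0 || orientation_gain > 1)
    stop_config("orientation_gain must lie in (0, 1]")
  structure(list(name = name, orientation_gain = orientation_gain,
                 resp_freq = resp_freq, resp_amp = resp_amp,
                 resp_pattern = resp_pattern, hr_shift = hr_shift,
                 proportion = proportion),
            class = "scenario_spec")
}

#' Default seven-scenario taxonomy
#'
#' The seven posture/breathing conditions of the study design with their
#' dataset proportions expressed as exact segment-count ratios
#' (2816, 1199, 1077, 968, 571, 458, 432 out of 7521), which sum to one.
#' Orientation gains are monotone in how much cardiac chest-wall motion each
#' antenna orientation sees (chest-facing 1.0, chest-side 0.5, back 0.3).
#' Hypoxia-linked breathing states add +15/+20/+25 bpm to the baseline heart
#' rate and scale respiration per pattern.
#'
#' @return A list of seven [scenario_spec()] objects.
#' @export
default_scenarios <- function() {
  counts <- c(2816, 1199, 1077, 968, 571, 458, 432)
  p <- counts / sum(counts)
  list(
    scenario_spec("Sitting-CR-Eu",   1.0, 0.25, 1.8, "eupnea",        0,  p[1]),
    scenario_spec("Lat Decub-BR-Eu", 0.3, 0.22, 1.5, "eupnea",        0,  p[2]),
    scenario_spec("Lat Decub-CR-Eu", 1.0, 0.22, 1.5, "eupnea",        0,  p[3]),
    scenario_spec("Supine-CSR-Eu",   0.5, 0.20, 1.6, "eupnea",        0,  p[4]),
    scenario_spec("Supine-CSR-Ap",   0.5, 0.20, 1.6, "apnea",         15, p[5]),
    scenario_spec("Supine-CSR-Hy",   0.5, 0.20, 1.6, "hypoxic",       20, p[6]),
    scenario_spec("Supine-CSR-RSB",  0.5, 0.20, 1.6, "rapid_shallow", 25, p[7])
  )
}

check_proportions <- function(scenarios, tol = 1e-6) {
  p <- vapply(scenarios, `[[`, numeric(1), "proportion")
  if (abs(sum(p) - 1) > tol)
    stop_config("scenario proportions sum to ", format(sum(p)), ", not 1")
  p
}

#' Largest-remainder apportionment of segment counts
#'
#' Apportions `n` segments over scenarios proportionally, assigning floors
#' first and distributing the remainder by decreasing fractional part, ties
#' broken by list order. Counts always sum exactly to `n`.
#'
#' @param n total number of segments.
#' @param proportions numeric vector summing to 1 (within 1e-6).
#' @return Integer vector of counts, `sum == n`.
#' @export
apportion_counts <- function(n, proportions) {
  if (abs(sum(proportions) - 1) > 1e-6)
    stop_config("proportions must sum to 1")
  quota <- n * proportions
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    ord <- order(-frac, seq_along(frac))   # ties: list order
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
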