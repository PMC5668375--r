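# Calibration of the synthetic BCR (MFI) distribution. Under max-normalization
# the location parameter cancels, so only the log-sd and the saturation
# quantile are identifiable; these constants were solved numerically so that
# an 8342-cell draw has normalized mean ~0.0746 and median ~0.0436 with a
# >1000-fold dynamic range.
BCR_LOG_SD <- 1.043
BCR_SATURATION_QUANTILE <- 0.99866

#' Generate a synthetic BCR-level (MFI) distribution
#'
#' Draws per-cell surface-BCR fluorescence values from a saturation-censored
#' log-normal: log-normal variation across cells, with the brightest ~0.13%
#' clipped at a ceiling emulating the finite dynamic range of the detector.
#' Values are normalized by the maximum so the brightest cell is exactly 1.
#' At the default calibration an 8342-cell draw has normalized mean near
#' 0.0746, median near 0.0436, and a greater than 1000-fold range.
#'
#' @param n Number of cells (>= 1).
#' @param log_mean Mean of log fluorescence (cancels under normalization;
#'   kept for generating raw values on an instrument-like scale).
#' @param log_sd Standard deviation of log fluorescence (> 0 for a spread;
#'   0 collapses to a single value).
#' @param seed Integer seed (Mersenne-Twister).
#' @param saturation_quantile Log-normal quantile at which values are clipped
#'   (the detector ceiling); 1 disables censoring.
#' @return Numeric vector of `n` normalized BCR levels in (0, 1\] with
#'   `max(...) == 1`.
#' @examples
#' x <- generate_bcr_distribution(8342, seed = 1)
#' c(mean = mean(x), median = median(x))
#' @export
generate_bcr_distribution <- function(n, log_mean = 0, log_sd = BCR_LOG_SD,
                                      seed = 1,
                                      saturation_quantile = BCR_SATURATION_QUANTILE) {
  if (n < 1) abort("`n` must be at least 1")
  if (log_sd < 0) abort("`log_sd` must be non-negative")
  x <- withr::with_seed(seed, rlnorm(n, meanlog = log_mean, sdlog = log_sd))
  if (log_sd > 0 && saturation_quantile < 1) {
    cap <- qlnorm(saturation_quantile, meanlog = log_mean, sdlog = log_sd)
    x <- pmin(x, cap)
  }
  x / max(x)
}

#' Representative subsample of a BCR distribution
#'
#' Deterministic quantile thinning: returns the `(i - 0.5) / m` empirical
#' quantiles (inverse-ECDF, `type = 1`) of the parent distribution for
#' `i = 1..m`, giving a small cohort whose distribution tracks the parent's.
#' With `m` equal to the parent size this is the sorted parent itself; with
#' `m = 1` it is the parent's central order statistic.
#'
#' @param levels Parent BCR levels (numeric vector).
#' @param m Cohort size (<= `length(levels)`).
#' @return A [bcr_cohort] of `m` cells, ordered by BCR level.
#' @export
representative_subsample <- function(levels, m = 200) {
  n <- length(levels)
  if (m < 1) abort("`m` must be at least 1")
  if (m > n) abort("`m` must not exceed the parent size")
  q <- unname(quantile(levels, probs = (seq_len(m) - 0.5) / m, type = 1))
  bcr_cohort(q)
}

#' Default calibrated cohort
#'
#' Convenience wrapper reproducing the reference simulation setup: a parent
#' draw of 8342 cells from the calibrated BCR distribution thinned to a
#' representative cohort (200 cells by default).
#'
#' @param n_cells Cohort size.
#' @param n_parent Parent distribution size.
#' @param seed Integer seed for the parent draw.
#' @return A [bcr_cohort].
#' @export
synthetic_cohort <- function(n_cells = 200, n_parent = 8342, seed = 1) {
  representative_subsample(generate_bcr_distribution(n_parent, seed = seed),
                           m = n_cells)
}

# truncated-normal noise on [0, 1]; exact model value when sd = 0
add_truncnorm_noise <- function(y, sd) {
  if (sd == 0) return(y)
  lo <- pnorm(0, mean = y, sd = sd)
  hi <- pnorm(1, mean = y, sd = sd)
  qnorm(runif(length(y), lo, hi), mean = y, sd = sd)
}

new_observation_set <- function(x, y, sd, kind, extra = NULL) {
  obs <- tibble(x = x, y = y, sd = sd, kind = kind)
  if (!is.null(extra)) obs <- dplyr::bind_cols(obs, extra)
  structure(obs, class = c("bcr_observations", class(tibble())))
}

#' Synthetic viability observations
#'
#' Simulates the true viability surface for the given parameters and cohort,
#' then adds independent truncated-Gaussian noise on \[0, 1\] and attaches a
#' per-point standard deviation, emulating the mean-plus-SD summaries of a
#' small number of independent culture experiments. With the default 4 x 4
#' dose/time design this yields the 16-point observation set used by the
#' stimulated-stage fit.
#'
#' @param params_true A [bcr_params] generating the truth surface.
#' @param cohort A [bcr_cohort] (or numeric vector of initial levels).
#' @param doses Antibody doses (ug/ml).
#' @param times Observation times (hours).
#' @param noise_sd Noise standard deviation on the viability fraction
#'   (0 returns the simulated surface exactly).
#' @param seed Integer seed.
#' @param dt Integration step (hours).
#' @return A `bcr_observations` tibble with columns `x` (time, h), `y`
#'   (viability), `sd`, `kind = "viability"` and `dose` (ug/ml).
#' @export
generate_viability_observations <- function(params_true, cohort,
                                            doses = c(0, 0.3, 3, 10),
                                            times = c(0, 18, 48, 72),
                                            noise_sd = 0.02, seed = 1,
                                            dt = 0.01) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  surf <- dose_time_surface(cohort, doses, times, params_true, dt = dt)
  y <- withr::with_seed(seed, add_truncnorm_noise(surf$viability, noise_sd))
  new_observation_set(x = surf$time_h, y = y,
                      sd = if (noise_sd > 0) noise_sd else 1,
                      kind = "viability",
                      extra = tibble(dose = surf$dose_ug_ml))
}

#' Synthetic antibody-occupancy observations
#'
#' Emulates the two staining experiments behind the binding-constant fit.
#' `mode = "titration"`: plateau occupancy across doses, normalized so the
#' top dose reads 100% (fraction 1). `mode = "time_course"`: the occupancy
#' time course at a single dose from the closed-form binding model.
#' Gaussian noise truncated to \[0, 1\] is added.
#'
#' @param k2,k3 Binding constants (ml/ug/h and /h).
#' @param mode `"titration"` or `"time_course"`.
#' @param design Doses (ug/ml) for titration, or times (hours) for the time
#'   course.
#' @param dose Staining dose for the time course (ug/ml).
#' @param noise_sd Noise standard deviation (0 gives exact model values).
#' @param seed Integer seed.
#' @return A `bcr_observations` tibble (kind `"occupancy_titration"` or
#'   `"occupancy_time"`; the time course carries a `dose` column).
#' @export
generate_occupancy_observations <- function(k2, k3,
                                            mode = c("titration", "time_course"),
                                            design, dose = 1,
                                            noise_sd = 0.02, seed = 1) {
  mode <- match.arg(mode)
  if (length(design) < 1) abort("`design` must be non-empty")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  if (mode == "titration") {
    plateau <- equilibrium_occupancy(design, k2, k3)
    y0 <- plateau / equilibrium_occupancy(max(design), k2, k3)
    y <- withr::with_seed(seed, add_truncnorm_noise(y0, noise_sd))
    new_observation_set(x = design, y = y,
                        sd = if (noise_sd > 0) noise_sd else 1,
                        kind = "occupancy_titration")
  } else {
    y0 <- occupancy_closed_form(dose, design, k2, k3)
    y <- withr::with_seed(seed, add_truncnorm_noise(y0, noise_sd))
    new_observation_set(x = design, y = y,
                        sd = if (noise_sd > 0) noise_sd else 1,
                        kind = "occupancy_time",
                        extra = tibble(dose = dose))
  }
}

#' Synthetic BCR-level (MFI) decay observations
#'
#' Mean surface-BCR level during unstimulated culture, normalized to 1 at
#' time 0, decaying as `exp(-d1 * t)`, with truncated-Gaussian noise.
#' Used to exercise the decay-rate fit.
#'
#' @param d1 True degradation rate (/h).
#' @param times Observation times (hours).
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @return A `bcr_observations` tibble with `kind = "mfi_decay"`.
#' @export
generate_mfi_decay_observations <- function(d1, times = c(0, 18, 48, 72),
                                            noise_sd = 0.02, seed = 1) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  y0 <- bcr_level_at(times, 1, d1)
  y <- withr::with_seed(seed, add_truncnorm_noise(y0, noise_sd))
  new_observation_set(x = times, y = y,
                      sd = if (noise_sd > 0) noise_sd else 1,
                      kind = "mfi_decay")
}
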