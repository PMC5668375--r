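clamp_state <- function(B, C, S) {
  B <- min(max(B, 0), 1)
  C <- min(max(C, 0), B)
  S <- min(max(S, 0), 1)
  c(B, C, S)
}

#' One fixed-step Runge-Kutta update of a cell
#'
#' Advances a [cell_state] by `dt` hours with the classical 4-stage
#' Runge-Kutta scheme applied to [combined_rhs()], then clamps the state to
#' its invariant ranges (`bcr_level` and `signal_on` to \[0, 1\],
#' `bcr_bound` to \[0, bcr_level\]) to absorb floating-point excursions.
#' The `alive` flag is updated by the death rule: once `signal_on` falls
#' below `deadline` the cell is dead, and death is absorbing.
#'
#' @inheritParams combined_rhs
#' @param dt Step size (hours), must be positive.
#' @return The updated [cell_state].
#' @export
rk4_step <- function(state, anti_igm, params, dt) {
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be positive")
  params <- validate_bcr_params(params)
  y <- c(state$bcr_level, state$bcr_bound, state$signal_on)
  f <- function(y) {
    s <- list(bcr_level = y[1], bcr_bound = y[2], signal_on = y[3])
    unname(combined_rhs_raw(s, anti_igm, params))
  }
  k1 <- f(y)
  k2 <- f(y + 0.5 * dt * k1)
  k3 <- f(y + 0.5 * dt * k2)
  k4 <- f(y + dt * k3)
  y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  y <- clamp_state(y[1], y[2], y[3])
  alive <- state$alive && y[3] >= params$deadline
  structure(list(bcr_level = y[1], bcr_bound = y[2], signal_on = y[3],
                 alive = alive, t = state$t + dt),
            class = "cell_state")
}

# rhs without the per-call invariant checks (intermediate RK stages may sit
# just outside the invariant box; the clamp at the end of the step handles it)
combined_rhs_raw <- function(state, anti_igm, params) {
  B <- state$bcr_level; C <- state$bcr_bound; S <- state$signal_on
  bfree <- B - C
  f <- max(0, C - B * params$offset)
  c(-params$d1 * B,
    params$k2 * anti_igm * bfree - params$k3 * C,
    params$k1 * (1 - S) * bfree + params$k4 * (1 - S) * f - params$d2 * S)
}

snap_to_grid <- function(times, dt, nsteps) {
  k <- as.integer(round(times / dt))
  pmin(pmax(k, 0L), as.integer(nsteps))
}

#' Simulate a single cell
#'
#' Integrates one cell's trajectory from `t = 0` to `t_end` on a fixed grid
#' of step `dt`. The initial state mirrors the culture setup: `bcr_level =
#' bcr0`, no bound BCR, and `signal_on` equal to the initial BCR level (the
#' pre-culture signal correlates with BCR density). A cell is recorded dead
#' at the first grid time at which `signal_on < deadline` (strict), including
#' `t = 0`; death is absorbing. Requested `record_times` are snapped to the
#' nearest grid point.
#'
#' @param bcr0 Initial BCR level in (0, 1\].
#' @param anti_igm Antibody dose (ug/ml), constant over the culture.
#' @param params A [bcr_params].
#' @param t_end Culture duration (hours).
#' @param dt Integration step (hours); 0.01 h reproduces the reference
#'   simulation grid.
#' @param record_times Output times (hours); default is hourly plus `t_end`.
#' @return A tibble of class `bcr_trajectory` with columns `t`, `bcr_level`,
#'   `bcr_bound`, `signal_on`, `alive`, and attribute `death_time`
#'   (`NA` if the cell survives to `t_end`).
#' @examples
#' tr <- simulate_cell(1, 0, bcr_params_table1(), t_end = 72)
#' attr(tr, "death_time")
#' @export
simulate_cell <- function(bcr0, anti_igm, params, t_end = 72, dt = 0.01,
                          record_times = NULL) {
  if (t_end <= 0) abort("`t_end` must be positive")
  if (dt <= 0) abort("`dt` must be positive")
  if (bcr0 <= 0 || bcr0 > 1) abort("`bcr0` must lie in (0, 1]")
  if (anti_igm < 0) abort("`anti_igm` must be non-negative")
  params <- validate_bcr_params(params)
  nsteps <- round(t_end / dt)
  if (is.null(record_times)) record_times <- unique(c(seq(0, t_end, by = 1), t_end))
  steps <- sort(unique(snap_to_grid(record_times, dt, nsteps)))
  out <- .cell_trajectory_cpp(bcr0, anti_igm, params_vec(params), dt, steps)
  death <- out$death_time
  traj <- tibble(t = out$t, bcr_level = out$bcr_level,
                 bcr_bound = out$bcr_bound, signal_on = out$signal_on,
                 alive = if (is.na(death)) TRUE else out$t < death)
  structure(traj, death_time = death,
            class = c("bcr_trajectory", class(traj)))
}

#' Build a cohort of cells
#'
#' A cohort is an ordered set of cells identified by their initial BCR
#' levels, the representative sample over which viability is computed.
#'
#' @param bcr0 Numeric vector of initial BCR levels, each in (0, 1\].
#' @return A tibble of class `bcr_cohort` with columns `cell` and `bcr0`.
#' @export
bcr_cohort <- function(bcr0) {
  bcr0 <- as.numeric(bcr0)
  if (length(bcr0) < 1) abort("a cohort needs at least one cell")
  if (any(!is.finite(bcr0)) || any(bcr0 <= 0) || any(bcr0 > 1)) {
    abort("all initial BCR levels must lie in (0, 1]")
  }
  structure(tibble(cell = seq_along(bcr0), bcr0 = bcr0),
            class = c("bcr_cohort", class(tibble())))
}

cohort_levels <- function(cohort) {
  if (is.numeric(cohort)) return(bcr_cohort(cohort)$bcr0)
  if (is.data.frame(cohort)) {
    if (!"bcr0" %in% names(cohort)) abort("cohort data frame needs a `bcr0` column")
    if (nrow(cohort) < 1) abort("a cohort needs at least one cell")
    return(as.numeric(cohort$bcr0))
  }
  abort("`cohort` must be a numeric vector or a data frame with `bcr0`")
}

#' Per-cell death times for a cohort
#'
#' Integrates every cell of the cohort at a constant antibody dose and
#' returns the grid time at which each cell dies (`NA` for survivors).
#'
#' @param cohort A [bcr_cohort], a data frame with a `bcr0` column, or a
#'   numeric vector of initial levels.
#' @inheritParams simulate_cell
#' @return A tibble with columns `cell`, `bcr0`, `death_time`.
#' @export
cohort_death_times <- function(cohort, anti_igm, params, t_end = 72, dt = 0.01) {
  if (t_end <= 0) abort("`t_end` must be positive")
  if (dt <= 0) abort("`dt` must be positive")
  levels <- cohort_levels(cohort)
  params <- validate_bcr_params(params)
  dts <- .cohort_death_times_cpp(levels, anti_igm, params_vec(params), t_end, dt)
  tibble(cell = seq_along(levels), bcr0 = levels, death_time = dts)
}

#' Cohort viability over time
#'
#' Simulates every cell of the cohort at a constant antibody dose and
#' returns the fraction alive at each requested time (times snapped to the
#' integration grid). A cell whose initial signal is already below the death
#' threshold counts dead at `t = 0`, so simulated viability at time 0 can be
#' below 1.
#'
#' @inheritParams cohort_death_times
#' @param times Observation times (hours).
#' @return A tibble with columns `time_h` and `viability`.
#' @examples
#' simulate_cohort(c(0.5, 0.05, 0.005), 0, bcr_params_table1(),
#'                 times = c(0, 18, 48, 72))
#' @export
simulate_cohort <- function(cohort, anti_igm, params, times = c(0, 18, 48, 72),
                            dt = 0.01) {
  if (length(times) < 1 || any(times < 0)) {
    abort("`times` must be non-negative and non-empty")
  }
  t_end <- max(times)
  if (t_end <= 0) t_end <- dt  # all-zero times: one step suffices
  dd <- cohort_death_times(cohort, anti_igm, params, t_end = t_end, dt = dt)
  nsteps <- round(t_end / dt)
  snapped <- snap_to_grid(times, dt, nsteps) * dt
  viability <- vapply(snapped, function(tt) {
    mean(is.na(dd$death_time) | dd$death_time > tt)
  }, numeric(1))
  tibble(time_h = times, viability = viability)
}

#' Viability surface over a dose x time grid
#'
#' Runs [simulate_cohort()] once per dose and assembles the tidy viability
#' surface. Deterministic given the cohort and parameters.
#'
#' @inheritParams simulate_cohort
#' @param doses Antibody doses (ug/ml), each non-negative.
#' @return A tibble of class `bcr_viability` with columns `dose_ug_ml`,
#'   `time_h`, `viability`.
#' @examples
#' cohort <- synthetic_cohort(n_cells = 50)
#' surf <- dose_time_surface(cohort, doses = c(0, 3, 10),
#'                           times = c(0, 18, 48, 72),
#'                           params = bcr_params_table1())
#' @export
dose_time_surface <- function(cohort, doses, times, params, dt = 0.01) {
  if (any(doses < 0)) abort("`doses` must be non-negative")
  surf <- purrr::map_dfr(doses, function(a) {
    simulate_cohort(cohort, a, params, times = times, dt = dt) |>
      dplyr::mutate(dose_ug_ml = a, .before = 1)
  })
  structure(surf, class = c("bcr_viability", class(tibble())))
}
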