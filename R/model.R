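#' Surface BCR level under first-order decay
#'
#' In unstimulated culture the surface BCR level of each cell decays
#' exponentially, `bcr0 * exp(-d1 * t)`: with synthesis shut down, net
#' internalization/degradation dominates and the level falls at rate `d1`.
#'
#' @param t Time since culture start (hours); vectorized.
#' @param bcr0 Initial BCR level (dimensionless, in \[0, 1\]).
#' @param d1 Degradation rate (/h).
#' @return BCR level(s) at `t`.
#' @examples
#' bcr_level_at(72, 1, 0.01435)  # ~0.3558, a 64% reduction over 3 days
#' @export
bcr_level_at <- function(t, bcr0, d1) {
  if (any(t < 0)) abort("`t` must be non-negative")
  if (d1 < 0) abort("`d1` must be non-negative")
  if (any(bcr0 < 0 | bcr0 > 1)) abort("`bcr0` must lie in [0, 1]")
  bcr0 * exp(-d1 * t)
}

#' Tonic survival-signal derivative
#'
#' The survival signal is a conserved two-state pool: `signal_on` plus
#' `signal_off` sum to 1. Free surface BCR converts off to on at rate
#' `k1 * bcr_level`; the on-signal is consumed at rate `d2`:
#' `d signal_on/dt = k1 * (1 - signal_on) * bcr_level - d2 * signal_on`.
#'
#' @param signal_on Current survival signal (dimensionless, in \[0, 1\]).
#' @param bcr_level Current total BCR level.
#' @param k1 Tonic generation rate (/h).
#' @param d2 Consumption rate (/h).
#' @return Signal derivative (/h).
#' @export
tonic_rhs <- function(signal_on, bcr_level, k1, d2) {
  if (any(signal_on < 0 | signal_on > 1)) abort("`signal_on` must lie in [0, 1]")
  k1 * (1 - signal_on) * bcr_level - d2 * signal_on
}

#' Steady state of the tonic signal
#'
#' Algebraic fixed point of [tonic_rhs()] at a frozen BCR level:
#' `k1 * bcr_level / (k1 * bcr_level + d2)`. Monotone increasing in
#' `bcr_level` and `k1`, decreasing in `d2`; always below 1.
#'
#' @inheritParams tonic_rhs
#' @return Steady-state `signal_on` in \[0, 1).
#' @export
tonic_steady_state <- function(bcr_level, k1, d2) {
  denom <- k1 * bcr_level + d2
  if (any(denom <= 0)) abort("`k1 * bcr_level + d2` must be positive")
  k1 * bcr_level / denom
}

#' Antibody-BCR binding kinetics
#'
#' Mass-action association/dissociation of a bivalent anti-IgM antibody with
#' free surface BCR:
#' `d bcr_bound/dt = k2 * anti_igm * (bcr_level - bcr_bound) - k3 * bcr_bound`.
#'
#' @param bcr_bound Crosslinked (antibody-bound) BCR level.
#' @param bcr_level Total BCR level; free BCR is `bcr_level - bcr_bound`.
#' @param anti_igm Antibody concentration (ug/ml), constant over the culture.
#' @param k2 Association rate (ml/ug/h).
#' @param k3 Dissociation rate (/h).
#' @return Bound-BCR derivative (/h).
#' @export
binding_rhs <- function(bcr_bound, bcr_level, anti_igm, k2, k3) {
  if (any(bcr_bound < 0) || any(bcr_bound > bcr_level)) {
    abort("`bcr_bound` must lie in [0, bcr_level]")
  }
  k2 * anti_igm * (bcr_level - bcr_bound) - k3 * bcr_bound
}

#' Closed-form BCR occupancy
#'
#' Fraction of total BCR crosslinked after time `t` of staining at a constant
#' antibody dose, assuming constant total BCR (the staining model):
#' `k2*A*(1 - exp(-(k2*A + k3)*t)) / (k2*A + k3)`. As `t -> Inf` this tends
#' to the binding-equilibrium fraction `A / (A + k3/k2)`.
#'
#' @inheritParams binding_rhs
#' @param t Staining time (hours); vectorized, as is `anti_igm`.
#' @return Occupied fraction of total BCR.
#' @examples
#' occupancy_closed_form(1, 1, 2.779, 3.145)  # ~plateau within 1 h at 1 ug/ml
#' @export
occupancy_closed_form <- function(anti_igm, t, k2, k3) {
  if (any(t < 0)) abort("`t` must be non-negative")
  if (any(anti_igm < 0)) abort("`anti_igm` must be non-negative")
  n <- max(length(anti_igm), length(t))
  kA <- rep_len(k2 * anti_igm, n)
  tt <- rep_len(t, n)
  rate <- kA + k3
  eq <- ifelse(rate > 0, kA / rate, 0)
  eq * (1 - exp(-rate * tt))
}

#' Equilibrium occupancy fraction
#'
#' Binding-equilibrium fraction of total BCR occupied at dose `A`:
#' `A / (A + k3/k2)`.
#'
#' @inheritParams occupancy_closed_form
#' @return Equilibrium occupied fraction.
#' @export
equilibrium_occupancy <- function(anti_igm, k2, k3) {
  if (any(anti_igm < 0)) abort("`anti_igm` must be non-negative")
  kA <- k2 * anti_igm
  ifelse(kA + k3 > 0, kA / (kA + k3), 0)
}

#' Fraction of equilibrium occupancy reached by time t
#'
#' The occupancy time course approaches its plateau exponentially with rate
#' `k2*A + k3`; the fraction of the plateau reached by time `t` is
#' `1 - exp(-(k2*A + k3)*t)`. With the fitted binding constants this
#' reproduces the saturation statements for the anti-IgM doses of interest
#' (about 95% of the plateau in 30 min at 1 ug/ml, 82% at 0.1 ug/ml, and
#' 99% in 9 min at 10 ug/ml).
#'
#' @inheritParams occupancy_closed_form
#' @return Fraction of the equilibrium occupancy reached (in \[0, 1\]).
#' @examples
#' saturation_fraction(1, 0.5, 2.779, 3.145)
#' @export
saturation_fraction <- function(anti_igm, t, k2, k3) {
  if (any(t < 0)) abort("`t` must be non-negative")
  if (any(anti_igm < 0)) abort("`anti_igm` must be non-negative")
  1 - exp(-(k2 * anti_igm + k3) * t)
}

#' Effective antigen-triggered signal input
#'
#' Crosslinked BCR below the activation threshold produces no effective
#' survival signal: the input to the `k4` term is
#' `max(0, bcr_bound - bcr_level * offset)`, zero whenever the occupancy
#' fraction is at or below `offset`.
#'
#' @inheritParams binding_rhs
#' @param offset Activation threshold as a fraction of total BCR.
#' @return Effective crosslinked-BCR input (same units as `bcr_bound`).
#' @export
effective_signal_input <- function(bcr_bound, bcr_level, offset) {
  if (any(bcr_bound < 0) || any(bcr_bound > bcr_level)) {
    abort("`bcr_bound` must lie in [0, bcr_level]")
  }
  if (any(offset < 0 | offset > 1)) abort("`offset` must lie in [0, 1]")
  pmax(0, bcr_bound - bcr_level * offset)
}

#' Cell state for the combined model
#'
#' A light container for one cell's state: total BCR level, antibody-bound
#' BCR, survival signal, alive flag and time. `signal_off` is not stored; it
#' is by definition `1 - signal_on`.
#'
#' @param bcr_level Total BCR level in \[0, 1\].
#' @param bcr_bound Bound BCR in \[0, bcr_level\].
#' @param signal_on Survival signal in \[0, 1\].
#' @param alive Logical.
#' @param t Time (hours).
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(bcr_level, bcr_bound = 0, signal_on = bcr_level,
                       alive = TRUE, t = 0) {
  if (bcr_level < 0 || bcr_level > 1) abort("`bcr_level` must lie in [0, 1]")
  if (bcr_bound < 0 || bcr_bound > bcr_level) {
    abort("`bcr_bound` must lie in [0, bcr_level]")
  }
  if (signal_on < 0 || signal_on > 1) abort("`signal_on` must lie in [0, 1]")
  structure(list(bcr_level = bcr_level, bcr_bound = bcr_bound,
                 signal_on = signal_on, alive = isTRUE(alive), t = t),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state t=%.3g h  bcr=%.4g  bound=%.4g  signal=%.4g  %s>\n",
              x$t, x$bcr_level, x$bcr_bound, x$signal_on,
              if (x$alive) "alive" else "dead"))
  invisible(x)
}

#' Combined-model derivatives
#'
#' Full right-hand side of the integrated tonic + antigen-triggered model for
#' one cell: BCR decay, binding kinetics on free BCR, and the survival-signal
#' balance in which free BCR drives the tonic term, thresholded crosslinked
#' BCR drives the `k4` term, and both generation terms draw on the shared
#' `signal_off = 1 - signal_on` pool. With `anti_igm = 0` and no bound BCR
#' this reduces exactly to the tonic-only model.
#'
#' @param state A [cell_state].
#' @param anti_igm Antibody dose (ug/ml).
#' @param params A [bcr_params].
#' @return Named numeric vector of derivatives
#'   `(bcr_level, bcr_bound, signal_on)` in /h.
#' @export
combined_rhs <- function(state, anti_igm, params) {
  params <- validate_bcr_params(params)
  B <- state$bcr_level; C <- state$bcr_bound; S <- state$signal_on
  if (C < 0 || C > B) abort("`bcr_bound` must lie in [0, bcr_level]")
  if (S < 0 || S > 1) abort("`signal_on` must lie in [0, 1]")
  bfree <- B - C
  f <- max(0, C - B * params$offset)
  c(bcr_level = -params$d1 * B,
    bcr_bound = params$k2 * anti_igm * bfree - params$k3 * C,
    signal_on = params$k1 * (1 - S) * bfree + params$k4 * (1 - S) * f -
      params$d2 * S)
}
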