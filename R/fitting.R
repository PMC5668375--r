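#' SD-weighted least-squares objective
#'
#' The error value `J = sum((y_i - f(x_i))^2 / sd_i^2)`: residuals are
#' down-weighted where the measurement SD is large and up-weighted where it
#' is small. Invariant under reordering of the observations.
#'
#' @param obs An observation tibble with columns `y` and `sd` (all `sd > 0`).
#' @param predictions Model predictions, same length and order as `obs$y`.
#' @return The scalar objective `J >= 0`.
#' @examples
#' obs <- tibble::tibble(y = c(1, 0.5), sd = c(0.5, 0.1))
#' weighted_objective(obs, c(0, 0.5))
#' @export
weighted_objective <- function(obs, predictions) {
  if (!all(c("y", "sd") %in% names(obs))) abort("`obs` needs columns `y` and `sd`")
  if (length(predictions) != nrow(obs)) {
    abort("`predictions` must match the number of observations")
  }
  if (any(obs$sd <= 0)) abort("all `sd` must be positive for weighted fitting")
  sum((obs$y - predictions)^2 / obs$sd^2)
}

#' Fit the BCR degradation rate
#'
#' One-dimensional weighted least squares for `d1` in the exponential-decay
#' model `y = exp(-d1 * t)` (BCR level normalized to 1 at time 0), minimized
#' by bounded search over `d1 >= 0`.
#'
#' @param obs An observation tibble (kind `mfi_decay`) with columns `x`
#'   (hours), `y` (normalized MFI) and `sd`.
#' @param upper Upper search bound for `d1` (/h).
#' @return A `bcr_fit` object; the estimate is in `$params["d1"]`.
#' @examples
#' obs <- generate_mfi_decay_observations(0.01435, noise_sd = 0)
#' coef(fit_decay_rate(obs))
#' @export
fit_decay_rate <- function(obs, upper = 1) {
  if (nrow(obs) < 2) abort("need at least 2 time points")
  if (all(obs$y == 0)) abort("all-zero observations cannot identify a decay rate")
  fobj <- function(d1) weighted_objective(obs, exp(-d1 * obs$x))
  # optimize() never evaluates exactly at the bounds; include 0 explicitly so
  # constant data give d1 = 0
  opt <- optimize(fobj, c(0, upper), tol = 1e-10)
  cand <- c(opt$minimum, 0)
  jv <- vapply(cand, fobj, numeric(1))
  best <- which.min(jv)
  new_bcr_fit(params = c(d1 = cand[best]), objective = jv[best],
              method = "wls", data_kind = "mfi_decay")
}

#' Fit the antibody-binding constants
#'
#' Two-step weighted least squares mirroring the staining experiments.
#' Step 1 fits the dissociation/association ratio (`k3/k2`) from a
#' titration of plateau occupancies (normalized so the top dose reads 100%).
#' Step 2 holds `r` fixed and fits the absolute scale `k2` from an occupancy
#' time course at a single dose via the closed-form binding model; `k3` is
#' then the ratio times `k2`.
#'
#' @param titration Observation tibble from a dose titration (columns `x` =
#'   dose in ug/ml, `y` = occupancy normalized to the top dose, `sd`); at
#'   least 3 doses.
#' @param time_course Observation tibble from a staining time course
#'   (columns `x` = hours, `y` = occupied fraction of total BCR, `sd`, and
#'   `dose` in ug/ml); at least 3 times.
#' @return A `bcr_fit` with `params = c(k2, k3)` and the ratio in
#'   `$details$ratio`.
#' @export
fit_binding_constants <- function(titration, time_course) {
  if (nrow(titration) < 3) abort("titration must span at least 3 doses")
  if (nrow(time_course) < 3) abort("time course must span at least 3 times")
  noiseless <- all(titration$sd == 1) || all(titration$sd == 0)
  ord <- order(titration$x)
  if (is.unsorted(titration$y[ord]) && noiseless) {
    warn("titration occupancy is not monotone in dose; fitting anyway")
  }
  amax <- max(titration$x)
  j_ratio <- function(r) {
    pred <- (titration$x / (titration$x + r)) / (amax / (amax + r))
    weighted_objective(titration, pred)
  }
  ratio <- minimize_log_scale(j_ratio, 1e-6, 1e3)

  dose <- if ("dose" %in% names(time_course)) time_course$dose[1] else 1
  j_scale <- function(k2) {
    pred <- occupancy_closed_form(dose, time_course$x, k2, ratio * k2)
    weighted_objective(time_course, pred)
  }
  k2 <- minimize_log_scale(j_scale, 1e-6, 1e3)
  new_bcr_fit(params = c(k2 = k2, k3 = ratio * k2),
              objective = j_scale(k2), method = "wls",
              data_kind = "occupancy",
              details = list(ratio = ratio, objective_ratio = j_ratio(ratio)))
}

#' Genetic-algorithm configuration
#'
#' Settings for the real-coded GA: unimodal normal distribution crossover
#' (UNDX) with minimal-generation-gap (MGG) selection. Defaults follow the
#' reference estimation setup: 100 individuals, parameters initialized
#' uniformly on their boxes (0-0.2 for rates and the death threshold, 0-1
#' for the activation threshold), warm-started parameters confined to
#' 50-150% of their previous values, and 10 random seeds run side by side.
#' UNDX internals use the standard literature values (sigma_xi = 0.5 along
#' the parent axis, sigma_eta = 0.35/sqrt(n) orthogonal to it).
#'
#' @param population_size Number of individuals (>= 3; UNDX needs 3 parents).
#' @param children_per_generation Offspring generated per MGG family.
#' @param undx_sigma_xi SD of the crossover component along the parent axis.
#' @param undx_sigma_eta SD of the orthogonal component, per unit distance of
#'   the third parent from the axis; `NULL` means `0.35/sqrt(n_params)`.
#' @param max_generations Hard cap on generations.
#' @param convergence_tol Relative gap between the population-mean and best
#'   objective below which the run is declared converged.
#' @param refit_band Fractional band `[low, high]` applied to warm-started
#'   parameters.
#' @param seeds Integer seeds for multi-seed consensus runs.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 100, children_per_generation = 50,
                      undx_sigma_xi = 0.5, undx_sigma_eta = NULL,
                      max_generations = 5000, convergence_tol = 1e-3,
                      refit_band = c(0.5, 1.5), seeds = 1:10) {
  if (population_size < 3) abort("`population_size` must be at least 3")
  if (children_per_generation < 2) abort("need at least 2 children per generation")
  if (convergence_tol <= 0) abort("`convergence_tol` must be positive")
  if (length(refit_band) != 2 || refit_band[1] >= refit_band[2]) {
    abort("`refit_band` must be an increasing pair")
  }
  structure(list(population_size = population_size,
                 children_per_generation = children_per_generation,
                 undx_sigma_xi = undx_sigma_xi,
                 undx_sigma_eta = undx_sigma_eta,
                 max_generations = max_generations,
                 convergence_tol = convergence_tol,
                 refit_band = refit_band,
                 seeds = seeds),
            class = "ga_config")
}

# 1-D minimization over a positive rate spanning several decades: a coarse
# log-spaced scan brackets the minimum (the objective can be nearly flat far
# from it, where plain golden-section search stalls), then local refinement.
minimize_log_scale <- function(f, lower, upper, n_grid = 200) {
  grid <- exp(seq(log(lower), log(upper), length.out = n_grid))
  jg <- vapply(grid, f, numeric(1))
  i <- which.min(jg)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, n_grid)]
  optimize(f, c(lo, hi), tol = 1e-12)$minimum
}

undx_children <- function(pop, n_children, sigma_xi, sigma_eta) {
  npop <- nrow(pop); n <- ncol(pop)
  idx <- sample(npop, 2)
  p1 <- pop[idx[1], ]; p2 <- pop[idx[2], ]
  mid <- (p1 + p2) / 2
  d <- p2 - p1
  dn <- sqrt(sum(d^2))
  children <- matrix(0, n_children, n)
  for (j in seq_len(n_children)) {
    i3 <- sample(setdiff(seq_len(npop), idx), 1)
    p3 <- pop[i3, ]
    if (dn > 0) {
      e1 <- d / dn
      v <- p3 - p1
      vperp <- v - sum(v * e1) * e1
      D <- sqrt(sum(vperp^2))
      z <- rnorm(n, 0, sigma_eta * D)
      z <- z - sum(z * e1) * e1
      children[j, ] <- mid + rnorm(1, 0, sigma_xi) * d + z
    } else {
      D <- sqrt(sum((p3 - mid)^2))
      children[j, ] <- mid + rnorm(n, 0, sigma_eta * D)
    }
  }
  list(children = children, parent_idx = idx)
}

roulette_inverse_rank <- function(J) {
  r <- rank(J, ties.method = "first")
  sample(length(J), 1, prob = 1 / r)
}

#' Real-coded genetic algorithm (UNDX + MGG)
#'
#' Minimizes `objective` over a box. Each generation an MGG family is formed
#' from two randomly drawn parents; offspring are produced by UNDX (midpoint
#' of the parents, a normal perturbation along the parent axis, and an
#' orthogonal normal component scaled by a third parent's distance from that
#' axis), clipped to the box. The family's best individual and a
#' roulette-selected survivor (probability proportional to inverse rank)
#' replace the two parents, so the population best never deteriorates. The
#' run terminates when the population-mean objective comes within
#' `convergence_tol` (relative) of the best, or at `max_generations`.
#' Non-finite objective values are ranked worst rather than dropped.
#'
#' @param objective Function mapping a parameter vector to a finite scalar.
#' @param lower,upper Box constraints (equal-length numeric vectors).
#' @param config A [ga_config].
#' @param seed Integer seed (Mersenne-Twister).
#' @param init Optional matrix of initial individuals (rows), e.g. to warm
#'   start; drawn uniformly on the box when `NULL`.
#' @param param_names Optional names for the parameter vector.
#' @return A `bcr_fit` with fields `params`, `objective`, `seed`,
#'   `generations`, `converged` and a per-generation `trace` tibble
#'   (generation, best and mean objective).
#' @examples
#' sphere <- function(x) sum(x^2)
#' fit <- ga_optimize(sphere, lower = rep(0, 3), upper = rep(0.2, 3),
#'                    config = ga_config(max_generations = 200), seed = 1)
#' fit$objective
#' @export
ga_optimize <- function(objective, lower, upper, config = ga_config(),
                        seed = 1, init = NULL, param_names = NULL) {
  n <- length(lower)
  if (length(upper) != n) abort("`lower` and `upper` must have equal length")
  if (any(upper <= lower)) abort("search box must be non-degenerate")
  eps <- 1e-12
  sigma_eta <- config$undx_sigma_eta %||% (0.35 / sqrt(n))
  safe_obj <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) Inf else v
  }
  withr::with_seed(seed, {
    pop <- init
    if (is.null(pop)) {
      pop <- matrix(runif(config$population_size * n, rep(lower, each = config$population_size),
                          rep(upper, each = config$population_size)),
                    config$population_size, n)
    }
    J <- apply(pop, 1, safe_obj)
    trace <- vector("list", config$max_generations)
    converged <- FALSE
    gen <- 0
    while (gen < config$max_generations) {
      gen <- gen + 1
      fam <- undx_children(pop, config$children_per_generation,
                           config$undx_sigma_xi, sigma_eta)
      kids <- fam$children
      # clip offspring to the box
      for (k in seq_len(n)) {
        kids[, k] <- pmin(pmax(kids[, k], lower[k]), upper[k])
      }
      Jk <- apply(kids, 1, safe_obj)
      fam_x <- rbind(pop[fam$parent_idx, , drop = FALSE], kids)
      fam_J <- c(J[fam$parent_idx], Jk)
      best <- which.min(fam_J)
      surv <- roulette_inverse_rank(fam_J)
      pop[fam$parent_idx[1], ] <- fam_x[best, ]
      J[fam$parent_idx[1]] <- fam_J[best]
      pop[fam$parent_idx[2], ] <- fam_x[surv, ]
      J[fam$parent_idx[2]] <- fam_J[surv]
      bestJ <- min(J)
      meanJ <- mean(J[is.finite(J)])
      trace[[gen]] <- c(generation = gen, best = bestJ, mean = meanJ)
      if ((meanJ - bestJ) / max(bestJ, eps) < config$convergence_tol) {
        converged <- TRUE
        break
      }
    }
    ibest <- which.min(J)
    params <- pop[ibest, ]
    if (!is.null(param_names)) names(params) <- param_names
    new_bcr_fit(params = params, objective = J[ibest], method = "ga",
                seed = seed, generations = gen, converged = converged,
                details = list(
                  trace = tibble::as_tibble(do.call(rbind, trace[seq_len(gen)])),
                  lower = lower, upper = upper))
  })
}

viability_ssd_objective <- function(obs, cohort, base_params, free, dt) {
  levels <- cohort_levels(cohort)
  doses <- if ("dose" %in% names(obs)) obs$dose else rep(0, nrow(obs))
  split_idx <- split(seq_len(nrow(obs)), doses)
  function(theta) {
    p <- base_params
    p[free] <- theta
    p <- validate_bcr_params(p)
    err <- 0
    for (d in names(split_idx)) {
      rows <- split_idx[[d]]
      sim <- simulate_cohort(levels, as.numeric(d), p,
                             times = obs$x[rows], dt = dt)
      err <- err + sum((sim$viability - obs$y[rows])^2)
    }
    err
  }
}

#' First-stage GA fit: tonic parameters from unstimulated survival
#'
#' Estimates `(k1, d2, deadline)` from dose-0 viability observations by
#' embedding the cohort simulation in [ga_optimize()] over the 0-0.2 box,
#' with `d1` fixed from the decay fit. The objective is the plain sum of
#' squared viability differences.
#'
#' @param viability_obs Observation tibble (dose 0 only) with columns `x`
#'   (hours) and `y` (viability fraction).
#' @param cohort A [bcr_cohort] or numeric vector of initial BCR levels.
#' @param d1 Fixed degradation rate (/h).
#' @param config A [ga_config].
#' @param seed Integer seed; defaults to the first configured seed.
#' @param dt Integration step (hours).
#' @return A `bcr_fit` over `(k1, d2, deadline)`.
#' @export
fit_tonic_stage <- function(viability_obs, cohort, d1, config = ga_config(),
                            seed = config$seeds[1], dt = 0.01) {
  if ("dose" %in% names(viability_obs) && any(viability_obs$dose != 0)) {
    abort("the tonic stage uses dose-0 observations only")
  }
  base <- list(d1 = d1, k1 = 0, k2 = 0, k3 = 0, k4 = 0, d2 = 0,
               offset = 0, deadline = 0)
  free <- c("k1", "d2", "deadline")
  obj <- viability_ssd_objective(viability_obs, cohort, base, free, dt)
  fit <- ga_optimize(obj, lower = rep(0, 3), upper = rep(0.2, 3),
                     config = config, seed = seed, param_names = free)
  fit$data_kind <- "viability_dose0"
  fit
}

#' Second-stage GA fit: full model from stimulated survival
#'
#' Estimates `(k1, d2, deadline, k4, offset)` from the dose x time viability
#' design (the 16-point set in the reference setup), warm-started from a
#' first-stage fit: `k1`, `d2` and `deadline` are confined to the
#' `refit_band` (default 50-150%) around their first-stage values, `k4`
#' searches 0-0.2 and `offset` 0-1. `d1`, `k2` and `k3` stay fixed at their
#' directly fitted values.
#'
#' @param viability_obs Observation tibble with columns `x` (hours), `y`
#'   (viability) and `dose` (ug/ml), including dose 0.
#' @param cohort A [bcr_cohort] or numeric vector.
#' @param warm First-stage `bcr_fit` (params `k1`, `d2`, `deadline`).
#' @param d1,k2,k3 Fixed directly fitted constants.
#' @param config A [ga_config].
#' @param seed Integer seed.
#' @param dt Integration step (hours).
#' @return A `bcr_fit` over `(k1, d2, deadline, k4, offset)`.
#' @export
fit_stimulated_stage <- function(viability_obs, cohort, warm, d1, k2, k3,
                                 config = ga_config(),
                                 seed = config$seeds[1], dt = 0.01) {
  if (!"dose" %in% names(viability_obs)) abort("`viability_obs` needs a `dose` column")
  if (!any(viability_obs$dose == 0)) abort("the design must include dose 0")
  w <- coef(warm)
  if (!all(c("k1", "d2", "deadline") %in% names(w))) {
    abort("`warm` must carry k1, d2 and deadline")
  }
  band <- config$refit_band
  free <- c("k1", "d2", "deadline", "k4", "offset")
  lower <- c(w[c("k1", "d2", "deadline")] * band[1], 0, 0)
  upper <- c(pmin(w[c("k1", "d2", "deadline")] * band[2], 1), 0.2, 1)
  names(lower) <- names(upper) <- free
  base <- list(d1 = d1, k1 = 0, k2 = k2, k3 = k3, k4 = 0, d2 = 0,
               offset = 0, deadline = 0)
  obj <- viability_ssd_objective(viability_obs, cohort, base, free, dt)
  fit <- ga_optimize(obj, lower = unname(lower), upper = unname(upper),
                     config = config, seed = seed, param_names = free)
  fit$data_kind <- "viability_surface"
  fit
}

#' Multi-seed consensus of GA fits
#'
#' Averages fitted parameters across independently seeded runs and reports
#' the spread as a percentage of the mean (sample SD, n - 1 convention),
#' the reporting convention of the reference parameter table.
#'
#' @param results List of `bcr_fit` objects over the same parameters.
#' @return A tibble with columns `parameter`, `mean`, `sd_percent`, `n_seeds`.
#' @export
consensus <- function(results) {
  if (length(results) < 2) abort("consensus needs at least 2 results")
  mats <- do.call(rbind, lapply(results, coef))
  mu <- unname(colMeans(mats))
  tibble(parameter = colnames(mats),
         mean = mu,
         sd_percent = 100 * unname(apply(mats, 2, sd)) / mu,
         n_seeds = length(results))
}

new_bcr_fit <- function(params, objective, method, seed = NA_integer_,
                        generations = NA_integer_, converged = NA,
                        data_kind = NA_character_, details = list()) {
  structure(list(params = params, objective = objective, method = method,
                 seed = seed, generations = generations,
                 converged = converged, data_kind = data_kind,
                 details = details),
            class = "bcr_fit")
}

#' @export
print.bcr_fit <- function(x, ...) {
  cat(sprintf("<bcr_fit: %s%s>\n", x$method,
              if (!is.na(x$data_kind)) paste0(" on ", x$data_kind) else ""))
  print(x$params)
  cat(sprintf("objective: %.6g", x$objective))
  if (!is.na(x$generations)) {
    cat(sprintf("  generations: %d  converged: %s", x$generations, x$converged))
  }
  cat("\n")
  invisible(x)
}

#' @export
coef.bcr_fit <- function(object, ...) object$params

#' @describeIn ga_optimize Tidy the fitted parameters of a `bcr_fit`.
#' @param x A `bcr_fit`.
#' @param ... Unused.
#' @export
tidy.bcr_fit <- function(x, ...) {
  tibble(term = names(x$params) %||% paste0("p", seq_along(x$params)),
         estimate = unname(x$params))
}

#' @describeIn ga_optimize One-row fit summary of a `bcr_fit`.
#' @export
glance.bcr_fit <- function(x, ...) {
  tibble(objective = x$objective, method = x$method, seed = x$seed,
         generations = x$generations, converged = x$converged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
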