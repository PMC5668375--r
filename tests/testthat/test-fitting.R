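test_that("the weighted objective matches its definition and scaling laws", {
  obs <- tibble::tibble(y = c(1, 0.5, 0.2), sd = c(0.5, 0.1, 0.2))
  expect_equal(weighted_objective(obs[1, ], 0), 4)
  expect_equal(weighted_objective(obs, obs$y), 0)
  # reorder invariance
  idx <- c(3, 1, 2)
  expect_equal(weighted_objective(obs, c(0.9, 0.4, 0.1)),
               weighted_objective(obs[idx, ], c(0.9, 0.4, 0.1)[idx]))
  # doubling every SD divides J by 4
  obs2 <- obs; obs2$sd <- 2 * obs$sd
  expect_equal(weighted_objective(obs2, c(0, 0, 0)),
               weighted_objective(obs, c(0, 0, 0)) / 4)
  obs0 <- obs; obs0$sd[2] <- 0
  expect_error(weighted_objective(obs0, obs$y), "positive")
})

test_that("the decay-rate fit recovers a known rate and handles edge data", {
  obs <- generate_mfi_decay_observations(0.01435, times = c(0, 18, 48, 72),
                                         noise_sd = 0)
  fit <- fit_decay_rate(obs)
  # dense-grid oracle for the same weighted objective
  grid <- seq(0.010, 0.020, by = 1e-6)
  jg <- vapply(grid, function(d) sum((obs$y - exp(-d * obs$x))^2 / obs$sd^2),
               numeric(1))
  expect_lt(abs(coef(fit)[["d1"]] - grid[which.min(jg)]), 1e-6)
  expect_lt(abs(coef(fit)[["d1"]] - 0.01435), 1e-6)
  # constant observations fit no decay
  flat <- tibble::tibble(x = c(0, 24, 48), y = rep(1, 3), sd = rep(0.02, 3))
  expect_equal(coef(fit_decay_rate(flat))[["d1"]], 0)
  expect_error(fit_decay_rate(flat[1, ]), "at least 2")
  zero <- tibble::tibble(x = c(0, 24), y = c(0, 0), sd = c(1, 1))
  expect_error(fit_decay_rate(zero), "all-zero")
})

test_that("SD weighting changes the fit on heteroscedastic noisy data", {
  obs <- generate_mfi_decay_observations(0.02, times = c(0, 18, 48, 72),
                                         noise_sd = 0.05, seed = 4)
  uneq <- obs; uneq$sd <- c(0.01, 0.3, 0.01, 0.3)
  expect_false(isTRUE(all.equal(coef(fit_decay_rate(obs))[["d1"]],
                                coef(fit_decay_rate(uneq))[["d1"]])))
})

test_that("binding constants are recovered from noiseless staining data", {
  doses <- c(0.1, 0.3, 1, 3, 10, 30)
  tit <- generate_occupancy_observations(2.779, 3.145, "titration",
                                         design = doses, noise_sd = 0)
  tc <- generate_occupancy_observations(2.779, 3.145, "time_course",
                                        design = c(0.1, 0.25, 0.5, 0.75, 1),
                                        dose = 1, noise_sd = 0)
  fit <- fit_binding_constants(tit, tc)
  # the printed ratio to 4 significant figures
  expect_equal(signif(fit$details$ratio, 4), 1.132)
  # noiseless data: the generating constants are the global optimum (J = 0),
  # so recovery to <1% certifies the two-step minimization
  expect_lt(abs(coef(fit)[["k2"]] / 2.779 - 1), 0.01)
  expect_lt(abs(coef(fit)[["k3"]] / 3.145 - 1), 0.01)
  expect_lt(fit$objective, 1e-10)
  expect_error(fit_binding_constants(tit[1:2, ], tc), "3 doses")
  expect_error(fit_binding_constants(tit, tc[1:2, ]), "3 times")
})

test_that("the occupancy model is invariant under joint time/rate rescaling", {
  # Eq-level identifiability: doubling time while halving both rates
  tt <- c(0.2, 0.5, 1, 2)
  expect_equal(occupancy_closed_form(1, 2 * tt, 2.779 / 2, 3.145 / 2),
               occupancy_closed_form(1, tt, 2.779, 3.145))
})

test_that("the GA minimizes a convex benchmark and keeps candidates in the box", {
  seen <- new.env(); seen$bad <- 0
  sphere <- function(x) {
    if (any(x < -1e-12) || any(x > 0.2 + 1e-12)) seen$bad <- seen$bad + 1
    sum(x^2)
  }
  fit <- ga_optimize(sphere, lower = rep(0, 3), upper = rep(0.2, 3),
                     config = ga_config(children_per_generation = 10,
                                        max_generations = 500,
                                        convergence_tol = 1e-9),
                     seed = 1, param_names = c("a", "b", "c"))
  expect_lt(fit$objective, 1e-3)
  expect_equal(seen$bad, 0)
  expect_true(all(coef(fit) >= 0 & coef(fit) <= 0.2))
  # best-so-far objective is non-increasing (elitism within the MGG family)
  expect_true(all(diff(fit$details$trace$best) <= 1e-15))
})

test_that("GA runs are reproducible per seed and tolerate non-finite objectives", {
  rosen_box <- function(x) (1 - x[1])^2 + 5 * (x[2] - x[1]^2)^2
  cfg <- ga_config(children_per_generation = 10, max_generations = 100)
  f1 <- ga_optimize(rosen_box, c(0, 0), c(1, 1), cfg, seed = 11)
  f2 <- ga_optimize(rosen_box, c(0, 0), c(1, 1), cfg, seed = 11)
  expect_identical(coef(f1), coef(f2))
  # an objective with a non-finite pocket still completes
  holey <- function(x) if (x[1] > 0.4 && x[1] < 0.5) NaN else sum(x^2)
  fh <- ga_optimize(holey, c(0, 0), c(1, 1), cfg, seed = 3)
  expect_true(is.finite(fh$objective))
  expect_lt(fh$objective, 0.05)
})

test_that("GA config invariants are enforced", {
  expect_error(ga_config(population_size = 2), "at least 3")
  expect_error(ga_config(convergence_tol = 0), "positive")
  expect_error(ga_config(refit_band = c(1.5, 0.5)), "increasing")
})

test_that("a small tonic-stage fit beats the truth objective and stays in the box", {
  co <- synthetic_cohort(n_cells = 20, seed = 2)
  truth <- stage1
  obs <- generate_viability_observations(truth, co, doses = 0,
                                         times = c(0, 18, 48, 72),
                                         noise_sd = 0.02, seed = 1)
  cfg <- ga_config(children_per_generation = 20, max_generations = 200)
  fit <- fit_tonic_stage(obs, co, d1 = truth$d1, config = cfg, seed = 1)
  est <- coef(fit)
  expect_true(all(est >= 0 & est <= 0.2))
  # optimizer contract: no worse than the generating parameters
  sim_truth <- simulate_cohort(co, 0, truth, times = c(0, 18, 48, 72))
  j_truth <- sum((sim_truth$viability - obs$y)^2)
  expect_lte(fit$objective, j_truth)
  expect_error(fit_tonic_stage(dplyr::mutate(obs, dose = 3), co, 0.01),
               "dose-0")
})

test_that("k4 is poorly identified without the saturating dose", {
  # profile the viability SSD along k4 (other parameters at truth): dropping
  # the 10 ug/ml rows flattens the profile, since at sub-saturating doses the
  # occupancy barely clears the activation threshold
  truth <- tbl1
  k4_grid <- c(0, 0.05, 0.1, 0.1294, 0.2)
  profile_ssd <- function(doses) {
    obs <- generate_viability_observations(truth, small_cohort, doses = doses,
                                           noise_sd = 0, seed = 1)
    vapply(k4_grid, function(k4v) {
      p <- truth; p$k4 <- k4v
      surf <- dose_time_surface(small_cohort, doses, c(0, 18, 48, 72),
                                validate_params_for_test(p))
      sum((surf$viability - obs$y)^2)
    }, numeric(1))
  }
  with10 <- profile_ssd(c(0, 0.3, 3, 10))
  without10 <- profile_ssd(c(0, 0.3, 3))
  expect_lt(diff(range(without10)), diff(range(with10)) / 3)
})

test_that("consensus averaging reports percent sample SD", {
  f <- function(v) structure(list(params = c(k1 = v), objective = 0,
                                  method = "ga"), class = "bcr_fit")
  same <- consensus(list(f(0.1), f(0.1), f(0.1)))
  expect_equal(same$sd_percent, 0)
  two <- consensus(list(f(0.1), f(0.3)))
  expect_equal(two$mean, 0.2)
  expect_equal(two$sd_percent, 50 * sqrt(2))
  expect_error(consensus(list(f(1))), "at least 2")
})

test_that("tidy and glance summarize fits", {
  obs <- generate_mfi_decay_observations(0.02, noise_sd = 0)
  fit <- fit_decay_rate(obs)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term, "d1")
  gl <- glance(fit)
  expect_named(gl, c("objective", "method", "seed", "generations", "converged"))
  expect_equal(gl$method, "wls")
})
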