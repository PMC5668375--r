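test_that("a single RK4 step matches the linear-decay expansion and rejects dt <= 0", {
  # pure consumption: k1 = k4 = 0 decouples the signal, dS/dt = -d2*S
  p <- bcr_params(d1 = 0, k1 = 0, k2 = 0, k3 = 0, k4 = 0, d2 = 0.1543,
                  offset = 0, deadline = 0)
  st <- cell_state(1, signal_on = 1)
  out <- rk4_step(st, 0, p, dt = 0.01)
  expect_lt(abs(out$signal_on - exp(-0.1543 * 0.01)), 1e-12)  # O(dt^5) local error
  expect_equal(out$t, 0.01)
  expect_error(rk4_step(st, 0, p, dt = 0), "positive")
  expect_error(rk4_step(st, 0, p, dt = -0.1), "positive")
})

test_that("R and C++ integration paths agree step for step", {
  p <- tbl1
  st <- cell_state(0.8, signal_on = 0.8)
  for (k in 1:20) st <- rk4_step(st, 3, p, dt = 0.01)
  tr <- simulate_cell(0.8, 3, p, t_end = 0.2, dt = 0.01, record_times = 0.2)
  expect_equal(st$bcr_level, tr$bcr_level[1], tolerance = 1e-12)
  expect_equal(st$bcr_bound, tr$bcr_bound[1], tolerance = 1e-12)
  expect_equal(st$signal_on, tr$signal_on[1], tolerance = 1e-12)
})

test_that("RK4 reproduces exponential BCR decay to within 1e-8 relative over 72 h", {
  tr <- simulate_cell(1, 0, tbl1, t_end = 72, dt = 0.01, record_times = c(24, 48, 72))
  expect_lt(max(abs(tr$bcr_level - exp(-tbl1$d1 * tr$t)) / exp(-tbl1$d1 * tr$t)),
            1e-8)
})

test_that("full combined trajectory agrees with an adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  p <- tbl1
  f <- function(t, y, parms) {
    st <- list(bcr_level = y[1], bcr_bound = y[2], signal_on = y[3])
    list(unname(combined_rhs(st, 3, p)))
  }
  ts <- c(0, 1, 6, 24, 72)
  ref <- deSolve::ode(c(B = 0.8, C = 0, S = 0.8), ts, f, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  tr <- simulate_cell(0.8, 3, p, t_end = 72, dt = 0.01, record_times = ts)
  expect_lt(max(abs(tr$bcr_level - ref[, "B"])), 1e-7)
  expect_lt(max(abs(tr$bcr_bound - ref[, "C"])), 1e-7)
  expect_lt(max(abs(tr$signal_on - ref[, "S"])), 1e-7)
})

test_that("the death rule is strict, absorbing, and applied at culture start", {
  p <- tbl1
  # initial signal below the threshold: dead at t = 0
  tr <- simulate_cell(0.005, 0, p, t_end = 1)
  expect_equal(attr(tr, "death_time"), 0)
  expect_false(any(tr$alive))
  # deadline 0: signal stays positive, every cell survives
  p0 <- p; p0$deadline <- 0
  tr0 <- simulate_cell(0.005, 0, validate_params_for_test(p0), t_end = 72)
  expect_true(is.na(attr(tr0, "death_time")))
  # a bright unstimulated cell survives the whole culture
  tr1 <- simulate_cell(1, 0, p, t_end = 72)
  expect_true(is.na(attr(tr1, "death_time")))
  # and its late signal sits near the quasi-steady tonic level, above deadline
  s72 <- tr1$signal_on[tr1$t == 72]
  # the signal lags the decaying BCR, so it sits slightly above the
  # instantaneous fixed point
  qss <- tonic_steady_state(exp(-p$d1 * 72), p$k1, p$d2)
  expect_lt(abs(s72 - qss), 0.01)
  expect_gt(s72, qss)
  expect_gt(s72, p$deadline)
  expect_error(simulate_cell(1, 0, p, t_end = 0), "positive")
  expect_error(simulate_cell(0, 0, p), "bcr0")
})

test_that("fine-step integration confirms cell fates", {
  fates_coarse <- cohort_death_times(small_cohort, 0, tbl1, dt = 0.01)
  fates_fine <- cohort_death_times(small_cohort, 0, tbl1, dt = 0.001)
  expect_equal(is.na(fates_coarse$death_time), is.na(fates_fine$death_time))
})

test_that("cohort viability counts alive cells over the cohort size", {
  # 80 of 200 alive reads 40%
  expect_equal(viability_at(c(rep(NA_real_, 80), rep(10, 120)), 24), 0.4)
  p <- tbl1
  # all levels below deadline: dead from the start
  dead <- simulate_cohort(rep(0.004, 5), 0, p, times = c(0, 18, 48))
  expect_equal(dead$viability, rep(0, 3))
  # all levels comfortably above: full viability at t = 0
  alive0 <- simulate_cohort(c(0.5, 0.8, 1), 0, p, times = 0)
  expect_equal(alive0$viability, 1)
  expect_error(simulate_cohort(numeric(0), 0, p, times = 0), "at least one")
})

test_that("viability is non-increasing in time and non-decreasing in initial BCR", {
  for (a in c(0, 1, 10)) {
    dd <- cohort_death_times(small_cohort, a, tbl1)
    times <- c(0, 6, 18, 30, 48, 60, 72)
    v <- vapply(times, function(tt) viability_at(dd$death_time, tt), numeric(1))
    expect_true(all(diff(v) <= 0))
    # cohort is sorted by bcr0: death times must be non-decreasing
    dt_ord <- dd$death_time[order(dd$bcr0)]
    dt_ord[is.na(dt_ord)] <- 1e9  # survivors: later than any finite death
    expect_true(all(diff(dt_ord) >= 0))
  }
})

test_that("halving the integration step changes no cell's fate", {
  for (a in c(0, 0.3, 3, 10)) {
    d1 <- cohort_death_times(small_cohort, a, tbl1, dt = 0.01)$death_time
    d2 <- cohort_death_times(small_cohort, a, tbl1, dt = 0.005)$death_time
    for (tt in c(0, 18, 48, 72)) {
      expect_equal(is.na(d1) | d1 > tt, is.na(d2) | d2 > tt)
    }
  }
})

test_that("the dose-time surface is deterministic and reduces to the tonic curve at dose 0", {
  s1 <- dose_time_surface(small_cohort, c(0, 3), c(0, 24, 72), tbl1)
  s2 <- dose_time_surface(small_cohort, c(0, 3), c(0, 24, 72), tbl1)
  expect_identical(s1, s2)
  tonic <- simulate_cohort(small_cohort, 0, tbl1, times = c(0, 24, 72))
  expect_equal(dplyr::filter(s1, dose_ug_ml == 0)$viability, tonic$viability)
  expect_error(dose_time_surface(small_cohort, -1, 0, tbl1), "non-negative")
})

test_that("an offset of 1 suppresses the crosslinked signal entirely", {
  p1 <- tbl1; p1$offset <- 1
  p1 <- validate_params_for_test(p1)
  surf <- dose_time_surface(small_cohort, c(0, 10, 30), c(0, 18, 48, 72), p1)
  # with the crosslinked branch gated off, higher dose can only sequester BCR
  # away from the tonic term, so stimulated viability cannot exceed dose 0
  base <- dplyr::filter(surf, dose_ug_ml == 0)$viability
  for (a in c(10, 30)) {
    expect_true(all(dplyr::filter(surf, dose_ug_ml == a)$viability <= base))
  }
})

test_that("a weakened tonic rate lowers the unstimulated survival curve", {
  p <- stage1
  p_ibr <- stage1; p_ibr$k1 <- 0.009523  # ~40% of the first-stage k1
  p_ibr <- validate_params_for_test(p_ibr)
  v <- simulate_cohort(full_cohort, 0, p, times = c(18, 48, 72))$viability
  v_ibr <- simulate_cohort(full_cohort, 0, p_ibr, times = c(18, 48, 72))$viability
  expect_true(all(v_ibr < v))
})
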