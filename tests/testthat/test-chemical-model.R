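test_that("heat-kernel superposition matches closed forms", {
  rel <- data.frame(x = 0, y = 0, t = 0, Q = 4 * pi)
  expect_equal(green_concentration(c(0, 0), 1, rel, D = 1, dim = 2), 1)
  # linearity: two releases equal the sum of single-release fields
  rel2 <- data.frame(x = c(0, 3), y = c(0, -1), t = c(0, 0.5), Q = c(2, 5))
  pts <- cbind(c(1, -2, 0.3), c(0.5, 1, -4))
  f12 <- green_concentration(pts, 2, rel2, D = 1.5, dim = 2)
  f1 <- green_concentration(pts, 2, rel2[1, ], D = 1.5, dim = 2)
  f2 <- green_concentration(pts, 2, rel2[2, ], D = 1.5, dim = 2)
  expect_equal(f12, f1 + f2, tolerance = 1e-12)
  # evaluation at a release's own position and time flags infinity
  expect_equal(green_concentration(c(3, -1), 0.5, rel2, D = 1.5, dim = 2)[1],
               Inf)
})

test_that("the diffused field conserves the released mass", {
  rel <- data.frame(x = c(0, 2), y = c(0, 1), t = c(0, 0.2), Q = c(1, 3))
  h <- 0.1
  gx <- seq(-9, 11, by = h); gy <- seq(-9, 11, by = h)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  mass <- sum(green_concentration(pts, 1.2, rel, D = 1, dim = 2)) * h^2
  expect_equal(mass, 4, tolerance = 0.001)
})

test_that("event-driven front is causal with strictly increasing onsets", {
  p <- chemical_params(D = 1, Q = 1, C_th = 1e-4, tau_d = 0, dim = 2, d = 1)
  chain <- data.frame(x = as.numeric(0:7), y = 0)
  sim <- simulate_chemical_front(p, chain, init = 1L)
  expect_true(all(diff(sim$trigger_time) > 0))
  expect_true(all(sim$trigger_time >= 0))
  # exactly one release per nucleus
  expect_equal(sum(!is.na(sim$release_time)), 8L)
})

test_that("event-driven trigger times match the grid-PDE oracle within 2%", {
  pos <- data.frame(x = as.numeric(0:9), y = 0)
  p <- chemical_params(D = 1, Q = 1, C_th = 0.08, tau_d = 0, dim = 2, d = 1)
  sim <- simulate_chemical_front(p, pos, init = 1L)
  oracle <- chem_grid_oracle(pos, D = 1, Q = 1, C_th = 0.08,
                             sigma_r = 0.04, h = 0.04, t_end = 3)
  rel <- abs(oracle[-1] - sim$trigger_time[-1]) / sim$trigger_time[-1]
  expect_lt(max(rel), 0.02)
})

test_that("nondimensional groups follow their definitions", {
  expect_equal(nondim_threshold(1, 2, 1, dim = 2), 4)
  expect_equal(nondim_threshold(1, 2, 1, dim = 3), 8)   # cubic in 3D
  expect_equal(nondim_threshold(1, 2, 2, dim = 2), 2)   # doubling Q halves
  expect_error(nondim_threshold(1, 2, 1, dim = 4), "dim")
  expect_equal(nondim_speed(2, 3, 6), 1)
  expect_equal(dim_speed(1, 3, 6), 2)
})

test_that("dimensionless speed collapses across dimensional parameters", {
  v_stars <- c(
    measure_chem_front_speed(chemical_params(D = 1, Q = 1, C_th = 0.05,
                                             d = 1)) * 1 / 1,
    measure_chem_front_speed(chemical_params(D = 5, Q = 3, C_th = 0.05 * 3 / 4,
                                             d = 2)) * 2 / 5,
    measure_chem_front_speed(chemical_params(D = 0.5, Q = 2,
                                             C_th = 0.05 * 2 / 9,
                                             d = 3)) * 3 / 0.5)
  expect_lt(max(abs(v_stars / v_stars[1] - 1)), 0.01)
})

test_that("the front speed decreases with the dimensionless threshold", {
  vs <- vapply(c(0.02, 0.04, 0.06, 0.08, 0.1),
               function(cs) chem_speed_function(cs, 0), numeric(1))
  expect_true(all(diff(vs) < 0))
})

test_that("in the delay-dominated limit the front advances one spacing per delay", {
  v40 <- chem_speed_function(0.05, 40)
  v80 <- chem_speed_function(0.05, 80)
  expect_lt(abs(v40 * 40 - v80 * 80) / (v80 * 80), 0.1)
  expect_lt(abs(v80 * 80 - 1), 0.1)
})

test_that("Stokes-Einstein gives the classical value for water", {
  D <- stokes_einstein(1, temperature = 298, viscosity = 0.89e-3)
  expect_equal(D, 245, tolerance = 0.01)
  expect_equal(stokes_einstein(2) / stokes_einstein(1), 0.5,
               tolerance = 1e-12)
  Dcorr <- stokes_einstein(1, correction = function(R) 0.25)
  expect_equal(Dcorr, D / 4, tolerance = 1e-12)
})

test_that("zero-delay speeds increase with cycle as density doubles", {
  sched <- cycle_schedule(cycles = 10:13, base_spacing = 12, nu_spacing = 2)
  p <- chemical_params(D = 20, Q = 1, C_th = 5e-4, tau_d = 0, dim = 2)
  pred <- predict_speed_vs_cycle_chemical(p, sched, delay_mode = "zero")
  expect_true(all(diff(pred$speed) > 0))
  expect_true(all(diff(pred$C_star) < 0))
})

test_that("a small fixed delay gives a rise-then-level-off crossover", {
  sched <- cycle_schedule(cycles = 10:13, base_spacing = 12, nu_spacing = 2)
  p <- chemical_params(D = 20, Q = 1, C_th = 5e-4, tau_d = 0.3, dim = 2)
  pred <- suppressWarnings(
    predict_speed_vs_cycle_chemical(p, sched, delay_mode = "fixed"))
  ratios <- pred$speed[-1] / pred$speed[-4]
  expect_gt(ratios[1], 1.1)           # speeds still rise clearly early
  expect_lt(ratios[2], ratios[1])     # but the growth flattens late
  expect_lt(ratios[3], ratios[1])
})

test_that("at fixed C* the delay-dominated speed is set by the spacing", {
  # in the delay limit the front advances about one spacing per delay, so
  # with the dimensionless threshold held fixed across cycles the speed
  # d_n/tau_d decreases as the spacing shrinks
  sched <- cycle_schedule(cycles = 10:12, base_spacing = 12, nu_spacing = 2)
  D <- 20; tau <- 300
  v_n <- vapply(sched$cycles, function(n) {
    d_n <- cycle_spacing(sched, n)
    dim_speed(chem_speed_function(0.05, tau * D / d_n^2, n_nuclei = 24),
              d_n, D)
  }, numeric(1))
  expect_true(all(diff(v_n) < 0))
  d_n <- cycle_spacing(sched, sched$cycles)
  expect_lt(max(abs(v_n * tau / d_n - 1)), 0.15)
})

test_that("per-cycle delay fitting inverts the model and flags infeasibility", {
  sched <- cycle_schedule(cycles = 10:12, base_spacing = 12, nu_spacing = 2)
  p <- chemical_params(D = 20, Q = 1, C_th = 5e-4, dim = 2)
  tau_true <- c(2, 4, 1)
  truth <- predict_speed_vs_cycle_chemical(p, sched,
                                           delay_mode = "per-cycle",
                                           tau_by_cycle = tau_true)
  fit <- fit_delay_per_cycle(truth$speed, 10:12, p, sched)
  expect_true(all(fit$feasible))
  expect_lt(max(abs(fit$tau_d - tau_true) / tau_true), 0.05)
  # a speed above the zero-delay bound cannot be matched by any delay
  v0 <- fit$v_zero_delay[1]
  fit2 <- fit_delay_per_cycle(c(2 * v0), 10L, p,
                              cycle_schedule(cycles = 10L,
                                             base_spacing = 12))
  expect_false(fit2$feasible)
  expect_true(is.na(fit2$tau_d))
})
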