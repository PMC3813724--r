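make_two_front_events <- function(n_per_side = 100, v = 3, L = 500,
                                  noise = 0, seed = 1) {
  xs <- seq(2, L - 2, length.out = 2 * n_per_side)
  t0 <- pmin(xs, L - xs) / v
  if (noise > 0) t0 <- t0 + with_seed(seed, stats::rnorm(length(t0), 0,
                                                         noise))
  data.frame(x_um = xs, t_s = t0)
}

test_that("two-front fit is exact on noiseless symmetric events", {
  ev <- make_two_front_events(v = 3)
  ff <- fit_two_fronts(ev)
  expect_equal(ff$left$speed, 3, tolerance = 1e-9)
  expect_equal(ff$right$speed, 3, tolerance = 1e-9)
  expect_equal(ff$split, 250, tolerance = 30)
})

test_that("single-front data yields one populated and one empty fit", {
  ev <- data.frame(x_um = seq(0, 100, by = 5), t_s = seq(0, 100, by = 5) / 2)
  expect_warning(fit_two_fronts(ev), "single front")
  ff <- suppressWarnings(fit_two_fronts(ev))
  expect_true(is.na(ff$split))
  pops <- c(ff$left$n, ff$right$n)
  expect_equal(sort(pops), c(0L, 21L))
  expect_equal(max(ff$left$speed, ff$right$speed, na.rm = TRUE), 2,
               tolerance = 1e-9)
})

test_that("speeds are recovered within 2% under timing noise", {
  ev <- make_two_front_events(n_per_side = 100, v = 3, noise = 2, seed = 7)
  ff <- fit_two_fronts(ev)
  expect_lt(abs(ff$left$speed - 3) / 3, 0.02)
  expect_lt(abs(ff$right$speed - 3) / 3, 0.02)
})

test_that("fits are x-reflection and time-shift invariant", {
  ev <- make_two_front_events(n_per_side = 60, v = 2.2, noise = 1.5,
                              seed = 3)
  ff <- fit_two_fronts(ev)
  ev_ref <- transform(ev, x_um = 500 - x_um)
  ff_ref <- fit_two_fronts(ev_ref)
  expect_equal(ff_ref$left$speed, ff$right$speed, tolerance = 1e-9)
  expect_equal(ff_ref$right$speed, ff$left$speed, tolerance = 1e-9)
  ev_sh <- transform(ev, t_s = t_s + 55)
  ff_sh <- fit_two_fronts(ev_sh)
  expect_equal(ff_sh$left$speed, ff$left$speed, tolerance = 1e-9)
  expect_equal(ff_sh$left$intercept, ff$left$intercept + 55,
               tolerance = 1e-9)
})

test_that("mean fitted speed is unbiased over seeded noise replicates", {
  devs <- vapply(1:200, function(s) {
    ev <- make_two_front_events(n_per_side = 50, v = 3, noise = 2, seed = s)
    ff <- fit_two_fronts(ev)
    mean(c(ff$left$speed, ff$right$speed)) - 3
  }, numeric(1))
  expect_lt(abs(mean(devs)) / 3, 0.005)
})

test_that("anaphase/metaphase speed ratio is 1 for a shared front", {
  meta <- make_two_front_events(n_per_side = 80, v = 3, noise = 1, seed = 2)
  ana <- make_two_front_events(n_per_side = 80, v = 3, noise = 1, seed = 9)
  ana$t_s <- ana$t_s + 25
  r <- front_speed_ratio(fit_two_fronts(ana), fit_two_fronts(meta))
  expect_equal(nrow(r), 2L)
  expect_true(all(abs(r$ratio - 1) < 3 * r$se + 0.02))
  # a front twice as fast gives ratio 2, reciprocal when swapped
  ana2 <- make_two_front_events(n_per_side = 80, v = 6, noise = 0)
  r2 <- front_speed_ratio(fit_two_fronts(ana2), fit_two_fronts(meta))
  expect_equal(r2$ratio, c(2, 2), tolerance = 0.02)
  r2r <- front_speed_ratio(fit_two_fronts(meta), fit_two_fronts(ana2))
  expect_equal(r2r$ratio * r2$ratio, c(1, 1), tolerance = 0.02)
})

test_that("speed decay fit returns the generating per-cycle factor", {
  sp <- c(1, 0.71, 0.5041, 0.357911)
  fit <- fit_speed_decay(sp, 10:13)
  expect_equal(fit$factor, 0.71, tolerance = 1e-9)
  expect_equal(fit_speed_decay(c(2, 2, 2, 2), 10:13)$factor, 1,
               tolerance = 1e-12)
  noisy <- with_seed(4, sp * exp(stats::rnorm(4, 0, 0.05)))
  expect_lt(abs(fit_speed_decay(noisy, 10:13)$factor - 0.71) / 0.71, 0.05)
  expect_error(fit_speed_decay(c(1, -1, 1), 10:12), "positive")
})

test_that("nearest-neighbour spacing matches lattice and pair geometry", {
  expect_equal(nn_spacing(data.frame(x = c(0, 7), y = c(0, 0))), 7)
  geom <- embryo_geometry(length_x = 90, width_y = 50, pixel_size = 1,
                          frame_interval = 1)
  sched <- cycle_schedule(cycles = 10:13, base_spacing = 9)
  pos <- place_nuclei(geom, sched, 10, jitter_frac = 0, seed = 1)
  expect_equal(nn_spacing(pos), 9, tolerance = 1e-12)
  expect_error(nn_spacing(data.frame(x = c(1, 1), y = c(2, 2))),
               "duplicate")
})

test_that("spacing-law fit inverts the generator's decay exponent", {
  d <- c(8, 8 / sqrt(2), 4, 4 / sqrt(2))
  expect_equal(fit_spacing_law(d, 10:13)$nu, 2, tolerance = 1e-9)
  expect_equal(fit_spacing_law(c(5, 5, 5), 10:12)$nu, Inf)
  expect_warning(fit_spacing_law(c(4, 5, 6), 10:12), "increases")
  # round trip on generated lattices across cycles
  geom <- embryo_geometry(length_x = 400, width_y = 150, pixel_size = 1,
                          frame_interval = 1)
  sched <- cycle_schedule(cycles = 10:13, base_spacing = 12,
                          nu_spacing = 2)
  dn <- vapply(10:13, function(n)
    nn_spacing(place_nuclei(geom, sched, n, jitter_frac = 0, seed = 1)),
    numeric(1))
  expect_equal(dn[2] / dn[1], 2^(-1 / 2), tolerance = 0.01)
  expect_lt(abs(fit_spacing_law(dn, 10:13)$nu - 2) / 2, 0.01)
})

test_that("cycle-duration growth fit matches closed forms", {
  expect_equal(fit_cycle_durations(c(100, 200, 400, 800), 10:13)$rate,
               log(2), tolerance = 1e-9)
  expect_equal(fit_cycle_durations(c(300, 300, 300), 10:12)$rate, 0,
               tolerance = 1e-12)
  T0 <- 500 * exp(0.12 * (0:3))
  expect_lt(abs(fit_cycle_durations(T0, 10:13)$rate - 0.12) / 0.12, 0.02)
  expect_error(fit_cycle_durations(c(1, 0, 2), 10:12), "positive")
})

test_that("per-cycle interval between markers is cycle-independent", {
  # events generated with a constant metaphase-to-anaphase interval
  rows <- lapply(10:13, function(n) {
    ev <- make_two_front_events(n_per_side = 60, v = 3 * 0.71^(n - 10),
                                noise = 1, seed = n)
    rbind(transform(ev, marker = "metaphase", cycle = n),
          transform(ev, t_s = t_s + 180, marker = "anaphase", cycle = n))
  })
  ev <- do.call(rbind, rows)
  fits <- fit_fronts_by_cycle(ev)
  # interval from intercept difference at each pole
  ints <- vapply(10:13, function(n) {
    fa <- fits[fits$cycle == n & fits$marker == "anaphase", ]
    fm <- fits[fits$cycle == n & fits$marker == "metaphase", ]
    mean(fa$intercept - fm$intercept)
  }, numeric(1))
  expect_lt(max(abs(ints - 180)), 5)
})
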