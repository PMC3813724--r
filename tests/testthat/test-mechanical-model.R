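test_that("dipole tensor has the isotropic plus traceless structure", {
  expect_equal(dipole_source_tensor(2, 0, 1.1), diag(2, 2))
  expect_equal(dipole_source_tensor(0, 1, 0),
               matrix(c(0.5, 0, 0, -0.5), 2))
  for (phi in c(0, 0.4, 2)) {
    S <- dipole_source_tensor(3, 5, phi)
    expect_equal(sum(diag(S)), 6, tolerance = 1e-12)
    expect_equal(S[1, 2], S[2, 1])
  }
})

test_that("free Fourier modes decay at the analytic transverse and longitudinal rates", {
  med <- elastic_medium(mu = 1, lam = 1, gamma = 2, length_x = 8,
                        length_y = 8, h = 0.25)
  expect_equal(unname(displacement_diffusion_constants(1, 1, 2)),
               c(0.5, 1.5))
  xs <- (0:(med$nx - 1)) * med$h
  k <- 2 * pi * 2 / (med$nx * med$h)
  dt <- 0.3
  # pure transverse mode: u_y(x) = sin(kx)
  st <- displacement_state(med)
  st$uy_hat <- stats::fft(matrix(sin(k * xs), med$nx, med$ny))
  f <- displacement_field(evolve_displacement(st, dt))
  expect_equal(f$uy, matrix(sin(k * xs) * exp(-med$D_t * k^2 * dt),
                            med$nx, med$ny), tolerance = 1e-6)
  # pure longitudinal mode: u_x(x) = sin(kx)
  st <- displacement_state(med)
  st$ux_hat <- stats::fft(matrix(sin(k * xs), med$nx, med$ny))
  f <- displacement_field(evolve_displacement(st, dt))
  expect_equal(f$ux, matrix(sin(k * xs) * exp(-med$D_l * k^2 * dt),
                            med$nx, med$ny), tolerance = 1e-6)
  # superposition of both modes decays mode by mode
  st <- displacement_state(med)
  st$ux_hat <- stats::fft(matrix(sin(k * xs), med$nx, med$ny))
  st$uy_hat <- stats::fft(matrix(sin(2 * k * xs), med$nx, med$ny))
  f <- displacement_field(evolve_displacement(st, dt))
  expect_equal(f$ux, matrix(sin(k * xs) * exp(-med$D_l * k^2 * dt),
                            med$nx, med$ny), tolerance = 1e-6)
  expect_equal(f$uy, matrix(sin(2 * k * xs) * exp(-med$D_t * 4 * k^2 * dt),
                            med$nx, med$ny), tolerance = 1e-6)
  expect_equal(displacement_diffusion_constants(1, -1, 1)[["D_l"]], 1)
  expect_error(displacement_diffusion_constants(1, -3, 1), "stability")
})

test_that("dipoles carry no net force so the mean displacement is conserved", {
  med <- elastic_medium(length_x = 8, length_y = 8, h = 0.25)
  st <- displacement_state(med)
  st <- add_dipole(st, dipole_source_tensor(1, 0.7, 0.3), c(3, 5), 0.3)
  expect_equal(abs(st$fx_hat[1, 1]), 0)
  expect_equal(abs(st$fy_hat[1, 1]), 0)
  for (i in 1:5) st <- evolve_displacement(st, 0.1)
  f <- displacement_field(st)
  expect_equal(mean(f$ux), 0, tolerance = 1e-12)
  expect_equal(mean(f$uy), 0, tolerance = 1e-12)
})

test_that("stress field matches the constitutive law on known fields", {
  med <- elastic_medium(mu = 1.3, lam = 0.6, gamma = 1, length_x = 8,
                        length_y = 8, h = 0.25)
  # uniform translation: zero stress
  st <- displacement_state(med)
  st$ux_hat[1, 1] <- 5 * length(st$ux_hat)
  sf <- stress_field(st)
  expect_equal(max(abs(sf$sxx)), 0, tolerance = 1e-9)
  expect_equal(max(abs(sf$sxy)), 0, tolerance = 1e-9)
  # longitudinal mode u_x = A sin(kx): sxx = (lam + 2 mu) A k cos(kx),
  # syy = lam A k cos(kx), sxy = 0
  xs <- (0:(med$nx - 1)) * med$h
  k <- 2 * pi * 3 / (med$nx * med$h)
  st <- displacement_state(med)
  st$ux_hat <- stats::fft(matrix(0.2 * sin(k * xs), med$nx, med$ny))
  sf <- stress_field(st)
  expect_equal(sf$sxx[, 1], (med$lam + 2 * med$mu) * 0.2 * k * cos(k * xs),
               tolerance = 1e-8)
  expect_equal(sf$syy[, 1], med$lam * 0.2 * k * cos(k * xs),
               tolerance = 1e-8)
  expect_equal(max(abs(sf$sxy)), 0, tolerance = 1e-9)
})

test_that("largest principal stress matches 2x2 eigenvalues and is rotation invariant", {
  expect_equal(max_principal_stress(3, 1, 0), 3)
  expect_equal(max_principal_stress(0, 0, 2), 2)
  s <- matrix(c(1.3, 0.4, 0.4, -2), 2)
  for (ang in c(0.3, 1.2, 2.8)) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    sr <- R %*% s %*% t(R)
    expect_equal(max_principal_stress(sr[1, 1], sr[2, 2], sr[1, 2]),
                 max(eigen(s)$values), tolerance = 1e-12)
  }
})

test_that("an isotropic source produces a four-fold symmetric response", {
  med <- elastic_medium(length_x = 8, length_y = 8, h = 0.125)
  st <- displacement_state(med)
  st <- add_dipole(st, dipole_source_tensor(1, 0, 0),
                   c(4, 4), 0.25)
  for (i in 1:10) st <- evolve_displacement(st, 0.05)
  f <- displacement_field(st)
  mag <- sqrt(f$ux^2 + f$uy^2)
  # the source sits on a grid node: |u| must be symmetric under x/y swap
  # and reflections about the source
  expect_equal(mag, t(mag), tolerance = 1e-9)
  ctr <- 4 / med$h + 1
  row_right <- mag[ctr + 1:10, ctr]
  row_left <- mag[ctr - 1:10, ctr]
  expect_equal(row_right, row_left, tolerance = 1e-9)
})

test_that("rotating the dipole orientation rotates the response field", {
  med <- elastic_medium(length_x = 8, length_y = 8, h = 0.25)
  w <- 0.3
  st0 <- displacement_state(med)
  st0 <- add_dipole(st0, dipole_source_tensor(0, 1, 0), c(0, 0), w)
  st9 <- displacement_state(med)
  st9 <- add_dipole(st9, dipole_source_tensor(0, 1, pi / 2), c(0, 0), w)
  for (i in 1:6) {
    st0 <- evolve_displacement(st0, 0.05)
    st9 <- evolve_displacement(st9, 0.05)
  }
  f0 <- displacement_field(st0)
  f9 <- displacement_field(st9)
  n <- med$nx
  # phi = pi/2 is phi = 0 rotated by 90 degrees: u'(Rx) = R u(x) with
  # R = [[0,-1],[1,0]]; on the grid (ix,iy) -> (-iy, ix) mod n
  idx <- function(i) ((i) %% n) + 1L
  for (ix in c(0, 3, 7, 12)) for (iy in c(0, 2, 9)) {
    ux <- f0$ux[idx(ix), idx(iy)]; uy <- f0$uy[idx(ix), idx(iy)]
    ux2 <- f9$ux[idx(-iy), idx(ix)]; uy2 <- f9$uy[idx(-iy), idx(ix)]
    expect_equal(ux2, -uy, tolerance = 1e-9)
    expect_equal(uy2, ux, tolerance = 1e-9)
  }
})

test_that("mechanical v* decreases with the dimensionless threshold", {
  vs <- vapply(c(0.06, 0.1, 0.15, 0.2, 0.25),
               function(s) suppressWarnings(mech_speed_function(s)),
               numeric(1))
  expect_true(all(vs > 0))
  expect_true(all(diff(vs) < 0))
})

test_that("mechanical v* collapses across dimensional re-parameterizations", {
  v_stars <- c(
    suppressWarnings(measure_mech_front_speed(mu = 1, lam = 0, gamma = 1,
                                              d = 1, P = 1,
                                              sigma_th = 0.1)) * 1 / 1,
    suppressWarnings(measure_mech_front_speed(mu = 3, lam = 0, gamma = 1.5,
                                              d = 2, P = 5,
                                              sigma_th = 0.125)) * 2 / 2,
    suppressWarnings(measure_mech_front_speed(mu = 0.5, lam = 0, gamma = 2,
                                              d = 0.5, P = 2,
                                              sigma_th = 0.8)) * 0.5 / 0.25)
  expect_lt(max(abs(v_stars / v_stars[1] - 1)), 0.01)
})

test_that("isotropic fronts are round; anisotropic fronts are rougher", {
  lat <- expand.grid(x = seq(1.5, 14.5), y = seq(1.5, 14.5))
  med <- elastic_medium(length_x = 16, length_y = 16, h = 0.125)
  # radial scatter of the activation isochrons about a smooth t(r) trend,
  # converted to a fraction of the mean radius; radii are measured from
  # the initiating nucleus
  roughness <- function(mode, sigma_th) {
    par <- mechanical_params(med, sigma_th = sigma_th,
                             P = if (mode == "isotropic") 1 else 0,
                             A = if (mode == "isotropic") 0 else 1,
                             mode = mode, d = 1)
    sim <- simulate_mechanical_front(par, lat, initiation = "center",
                                     dt = 0.01, seed = 4)
    on <- sim$onsets
    src <- on[!is.na(on$t_on) & on$t_on == 0, ][1, ]
    on$r <- sqrt((on$x - src$x)^2 + (on$y - src$y)^2)
    sub <- on[!is.na(on$t_on) & on$t_on > 0 & on$r >= 2 & on$r <= 6, ]
    fit <- stats::lm(t_on ~ r + I(r^2), sub)
    slope_mid <- stats::coef(fit)[2] +
      2 * stats::coef(fit)[3] * mean(sub$r)
    unname(stats::sd(stats::resid(fit)) / abs(slope_mid) / mean(sub$r))
  }
  r_iso <- roughness("isotropic", 0.15)
  expect_lt(r_iso, 0.05)
  # anisotropic random-phi dipoles at a lower threshold (pure deviatoric
  # sources are weaker) still give far rougher isochrons
  r_aniso <- roughness("anisotropic", 0.03)
  expect_gt(r_aniso, r_iso)
})

test_that("both-ends initiation makes fronts meet at the embryo center", {
  med <- elastic_medium(length_x = 20, length_y = 4, h = 0.125,
                        bc = "mirror_x")
  par <- mechanical_params(med, sigma_th = 0.1, P = 1, d = 1)
  lat <- expand.grid(x = seq(0.5, 19.5), y = c(1.5, 2.5))
  sim <- simulate_mechanical_front(par, lat, initiation = "both-ends",
                                   dt = 0.02)
  on <- sim$onsets
  expect_true(all(!is.na(on$t_on)))
  tcol <- tapply(on$t_on, on$x, mean)
  xs <- as.numeric(names(tcol))
  # activation latest at the center, earliest at the ends
  expect_lt(abs(xs[which.max(tcol)] - 10), 2.1)
  half <- xs <= 10
  expect_true(all(diff(tcol[half]) >= 0))
})

test_that("displacement profile rises after onset towards a plateau, along x", {
  med <- elastic_medium(length_x = 24, length_y = 4, h = 0.125)
  par <- mechanical_params(med, sigma_th = 0.12, P = 1, d = 1)
  lat <- expand.grid(x = seq(0, 23), y = c(1.5, 2.5))
  prof <- predict_displacement_profile(par, lat, station_x = 10,
                                       initiation = which(lat$x == 0),
                                       dt = 0.02, max_time = 25)
  onset <- attr(prof, "onset")
  expect_true(is.finite(onset))
  pre <- prof$ux[prof$t <= onset]
  post <- prof$ux[prof$t > onset]
  expect_gt(max(abs(post)), 10 * max(abs(pre[-length(pre)]), 1e-12))
  # approaches a plateau: late increments shrink
  late <- abs(diff(utils::tail(prof$ux, 20)))
  early_rise <- max(abs(diff(prof$ux)))
  expect_lt(max(late), early_rise / 5)
  # y-averaged transverse displacement vanishes by symmetry
  expect_lt(max(abs(prof$uy)), 1e-8 * max(abs(prof$ux)))
})

test_that("sign-of-trend dichotomy: nu_visc controls whether fronts slow down", {
  sched <- cycle_schedule(cycles = 10:13, base_spacing = 12, nu_spacing = 2)
  P <- 12^2 / 0.1   # sigma* = 0.1 in the first cycle at sigma_th = 1
  p0 <- suppressWarnings(predict_speed_vs_cycle_mechanical(
    sched, D_first = 100, nu_visc = 0, sigma_th = 1, P = P))
  p3 <- suppressWarnings(predict_speed_vs_cycle_mechanical(
    sched, D_first = 100, nu_visc = 3, sigma_th = 1, P = P))
  expect_true(all(diff(p0$speed) >= 0))
  expect_true(all(diff(p3$speed) < 0))
})

test_that("fit_nu recovers the generating exponent and amplitude", {
  sched <- cycle_schedule(cycles = 10:13, base_spacing = 12, nu_spacing = 2)
  P <- 12^2 / 0.1
  truth <- suppressWarnings(predict_speed_vs_cycle_mechanical(
    sched, D_first = 80, nu_visc = 2.4, sigma_th = 1, P = P))
  fit <- suppressWarnings(fit_nu(truth$speed, truth$cycle, sched,
                                 sigma_th = 1, P = P))
  expect_lt(abs(fit$nu_visc - 2.4) / 2.4, 0.02)
  expect_lt(abs(fit$D_first - 80) / 80, 0.02)
  # constant speeds: the exponent that exactly cancels the per-cycle gain
  const <- rep(1.7, 4)
  fitc <- suppressWarnings(fit_nu(const, 10:13, sched, sigma_th = 1, P = P))
  expect_true(is.finite(fitc$nu_visc))
  predc <- suppressWarnings(predict_speed_vs_cycle_mechanical(
    sched, D_first = fitc$D_first, nu_visc = fitc$nu_visc, sigma_th = 1,
    P = P))
  expect_lt(max(abs(predc$speed - 1.7)) / 1.7, 0.1)
  # a pure scale change moves D_first but not nu
  fit2 <- suppressWarnings(fit_nu(2 * truth$speed, truth$cycle, sched,
                                  sigma_th = 1, P = P))
  expect_equal(fit2$nu_visc, fit$nu_visc, tolerance = 1e-9)
  expect_equal(fit2$D_first, 2 * fit$D_first, tolerance = 1e-9)
})

test_that("drag estimate scales with viscosity and inverse mesh size squared", {
  expect_equal(drag_estimate(1e-3, 2, 0.5) / drag_estimate(1e-3, 2, 1), 4)
  expect_equal(drag_estimate(2e-3, 1, 1) / drag_estimate(1e-3, 1, 1), 2)
  g1 <- drag_estimate(1e-3, 1, 0.2)
  g2 <- drag_estimate(1e-3, 1, 0.2) * 2
  d1 <- displacement_diffusion_constants(1, 0, g1)
  d2 <- displacement_diffusion_constants(1, 0, g2)
  expect_equal(unname(d1 / d2), c(2, 2))
})
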