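#' Overdamped elastic medium on a grid
#'
#' The cytoskeleton is modelled as a homogeneous linear elastic sheet
#' (shear modulus `mu`, Lamé modulus `lam`) immersed in a viscous fluid
#' exerting a drag `gamma` per unit volume per unit velocity.  In the
#' overdamped limit the displacement field obeys
#' `gamma du/dt = mu lap(u) + (mu + lam) grad(div u) + f`, i.e. vector
#' diffusion with transverse constant `D_t = mu/gamma` and longitudinal
#' constant `D_l = (2 mu + lam)/gamma`.  The solver is spectral: each
#' Fourier mode is split into longitudinal and transverse projections and
#' advanced with its exact exponential decay, so free relaxation is exact
#' per mode and the scheme is unconditionally stable.
#'
#' Boundary conditions: `"periodic"` (both directions) or `"mirror_x"`,
#' which doubles the domain in x and adds a reflected image to every source,
#' enforcing a slip wall at `x = 0` and `x = length_x` (zero normal
#' displacement and zero shear traction) — a computationally convenient
#' stand-in for the embryo's free poles that, like a free edge, transmits no
#' net x-force.
#'
#' @param mu Shear modulus (Pa), > 0.
#' @param lam Lamé first modulus (Pa); `2 mu + lam > 0` required.
#' @param gamma Damping constant (Pa s / µm^2), > 0.
#' @param length_x,length_y Domain extents (µm).
#' @param h Grid spacing (µm); extents are rounded to whole cells.
#' @param bc `"periodic"` or `"mirror_x"`.
#' @return Object of class `elastic_medium`.
#' @export
elastic_medium <- function(mu = 1, lam = 0, gamma = 1,
                           length_x = 24, length_y = 4, h = 0.125,
                           bc = c("periodic", "mirror_x")) {
  bc <- match.arg(bc)
  stop_if_not_positive(mu = mu, gamma = gamma, h = h,
                       length_x = length_x, length_y = length_y)
  if (2 * mu + lam <= 0) stop("stability requires 2*mu + lam > 0")
  Lx_phys <- length_x
  Lx <- if (bc == "mirror_x") 2 * length_x else length_x
  nx <- max(8L, round(Lx / h))
  ny <- max(8L, round(length_y / h))
  Lx <- nx * h; Ly <- ny * h
  fftfreq <- function(n, L) {
    i <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
    2 * pi * i[seq_len(n)] / L
  }
  kx <- fftfreq(nx, Lx)
  ky <- fftfreq(ny, Ly)
  KX <- matrix(kx, nx, ny)
  KY <- matrix(ky, nx, ny, byrow = TRUE)
  K2 <- KX^2 + KY^2
  structure(list(mu = mu, lam = lam, gamma = gamma,
                 D_t = mu / gamma, D_l = (2 * mu + lam) / gamma,
                 length_x = Lx_phys, length_y = Ly, Lx_internal = Lx,
                 nx = nx, ny = ny, h = h, bc = bc,
                 KX = KX, KY = KY, K2 = K2),
            class = "elastic_medium")
}

#' Transverse and longitudinal displacement diffusion constants
#'
#' @param mu Shear modulus (Pa).
#' @param lam Lamé modulus (Pa).
#' @param gamma Damping constant (Pa s / µm^2).
#' @return Named vector `c(D_t, D_l)` with `D_t = mu/gamma`,
#'   `D_l = (2 mu + lam)/gamma`.
#' @export
displacement_diffusion_constants <- function(mu, lam, gamma) {
  stop_if_not_positive(mu = mu, gamma = gamma)
  if (2 * mu + lam <= 0) stop("stability requires 2*mu + lam > 0")
  c(D_t = mu / gamma, D_l = (2 * mu + lam) / gamma)
}

#' Force-dipole stress tensor
#'
#' `S = P I + (A/2) [[cos 2 phi, sin 2 phi], [sin 2 phi, -cos 2 phi]]`:
#' an isotropic part of strength `P` plus a traceless anisotropic part of
#' strength `A` along the unit direction at angle `phi`.
#'
#' @param P Isotropic strength (stress x area).
#' @param A Anisotropic strength (stress x area).
#' @param phi Anisotropy direction (radians).
#' @return Symmetric 2x2 matrix.
#' @export
dipole_source_tensor <- function(P, A = 0, phi = 0) {
  matrix(c(P + A / 2 * cos(2 * phi), A / 2 * sin(2 * phi),
           A / 2 * sin(2 * phi), P - A / 2 * cos(2 * phi)), 2L)
}

#' Initialize a displacement state
#'
#' @param medium An [elastic_medium()].
#' @return Object of class `displacement_state` holding the spectral
#'   displacement field (zero), the cumulative spectral force density of
#'   active sources (zero) and the current time.
#' @export
displacement_state <- function(medium) {
  z <- matrix(0 + 0i, medium$nx, medium$ny)
  structure(list(ux_hat = z, uy_hat = z, fx_hat = z, fy_hat = z,
                 medium = medium, time = 0),
            class = "displacement_state")
}

# Add a Gaussian-smoothed force dipole (stress tensor S at position pos) to
# the state's active source field; under mirror_x bc the reflected image
# (x -> -x, S_xy -> -S_xy) is added automatically.
add_dipole <- function(state, S, pos, width) {
  med <- state$medium
  place <- function(S, x0, y0) {
    phase <- exp(-1i * (med$KX * x0 + med$KY * y0)) *
      exp(-med$K2 * width^2 / 2) / med$h^2
    state$fx_hat <<- state$fx_hat +
      1i * (med$KX * S[1L, 1L] + med$KY * S[1L, 2L]) * phase
    state$fy_hat <<- state$fy_hat +
      1i * (med$KX * S[2L, 1L] + med$KY * S[2L, 2L]) * phase
  }
  place(S, pos[1L], pos[2L])
  if (med$bc == "mirror_x") {
    Sm <- S
    Sm[1L, 2L] <- -S[1L, 2L]; Sm[2L, 1L] <- -S[2L, 1L]
    place(Sm, (-pos[1L]) %% med$Lx_internal, pos[2L])
  }
  state
}

#' Advance the displacement field
#'
#' Exact per-mode update over `dt` for the current (piecewise-constant)
#' source field: longitudinal and transverse projections relax towards
#' their source-balanced steady state at rates `D_l k^2` and `D_t k^2`.
#'
#' @param state A `displacement_state`.
#' @param dt Time step (s), > 0.
#' @return The advanced state.
#' @export
evolve_displacement <- function(state, dt) {
  med <- state$medium
  K2 <- med$K2
  nz <- K2 > 0
  dot <- matrix(0 + 0i, med$nx, med$ny)
  proj <- function(ax, ay) {
    dot[nz] <- (med$KX[nz] * ax[nz] + med$KY[nz] * ay[nz]) / K2[nz]
    list(lx = dot * med$KX, ly = dot * med$KY)
  }
  uL <- proj(state$ux_hat, state$uy_hat)
  fL <- proj(state$fx_hat, state$fy_hat)
  eL <- exp(-med$D_l * K2 * dt)
  eT <- exp(-med$D_t * K2 * dt)
  ssx <- ssy <- matrix(0 + 0i, med$nx, med$ny)
  ssx[nz] <- fL$lx[nz] / (med$gamma * med$D_l * K2[nz])
  ssy[nz] <- fL$ly[nz] / (med$gamma * med$D_l * K2[nz])
  new_Lx <- ssx + (uL$lx - ssx) * eL
  new_Ly <- ssy + (uL$ly - ssy) * eL
  tx <- state$ux_hat - uL$lx; ty <- state$uy_hat - uL$ly
  fTx <- state$fx_hat - fL$lx; fTy <- state$fy_hat - fL$ly
  stx <- sty <- matrix(0 + 0i, med$nx, med$ny)
  stx[nz] <- fTx[nz] / (med$gamma * med$D_t * K2[nz])
  sty[nz] <- fTy[nz] / (med$gamma * med$D_t * K2[nz])
  new_Tx <- stx + (tx - stx) * eT
  new_Ty <- sty + (ty - sty) * eT
  state$ux_hat <- new_Lx + new_Tx
  state$uy_hat <- new_Ly + new_Ty
  if (!all(is.finite(Re(state$ux_hat))))
    stop("displacement field diverged at dt = ", dt)
  state$time <- state$time + dt
  state
}

#' Real-space displacement field
#'
#' @param state A `displacement_state`.
#' @return List of matrices `ux`, `uy` (`nx x ny`, x along rows).
#' @export
displacement_field <- function(state) {
  n <- length(state$ux_hat)
  list(ux = Re(stats::fft(state$ux_hat, inverse = TRUE)) / n,
       uy = Re(stats::fft(state$uy_hat, inverse = TRUE)) / n)
}

#' Linear-elastic stress field of the current state
#'
#' `sigma_ij = lam (div u) delta_ij + mu (d_i u_j + d_j u_i)`, with
#' derivatives taken spectrally (the solver's native scheme); tensile stress
#' is positive.
#'
#' @param state A `displacement_state`.
#' @return List of matrices `sxx`, `syy`, `sxy`.
#' @export
stress_field <- function(state) {
  med <- state$medium
  n <- length(state$ux_hat)
  inv <- function(z) Re(stats::fft(z, inverse = TRUE)) / n
  dxux <- inv(1i * med$KX * state$ux_hat)
  dyuy <- inv(1i * med$KY * state$uy_hat)
  dxuy <- inv(1i * med$KX * state$uy_hat)
  dyux <- inv(1i * med$KY * state$ux_hat)
  div <- dxux + dyuy
  list(sxx = med$lam * div + 2 * med$mu * dxux,
       syy = med$lam * div + 2 * med$mu * dyuy,
       sxy = med$mu * (dxuy + dyux))
}

#' Largest principal stress
#'
#' Larger eigenvalue of a symmetric 2x2 stress tensor:
#' `(sxx + syy)/2 + sqrt(((sxx - syy)/2)^2 + sxy^2)`.  Vectorized.
#'
#' @param sxx,syy,sxy Tensor components (scalars or equal-shaped arrays).
#' @return The largest eigenvalue(s).
#' @export
max_principal_stress <- function(sxx, syy, sxy) {
  (sxx + syy) / 2 + sqrt(((sxx - syy) / 2)^2 + sxy^2)
}

# Bilinear interpolation of a periodic grid field at physical positions.
interp_grid <- function(field, h, xs, ys) {
  nx <- nrow(field); ny <- ncol(field)
  gx <- xs / h; gy <- ys / h
  i0 <- floor(gx); j0 <- floor(gy)
  fx <- gx - i0; fy <- gy - j0
  w <- function(i, j) field[cbind(i %% nx + 1L, j %% ny + 1L)]
  (1 - fx) * (1 - fy) * w(i0, j0) + fx * (1 - fy) * w(i0 + 1, j0) +
    (1 - fx) * fy * w(i0, j0 + 1) + fx * fy * w(i0 + 1, j0 + 1)
}

#' Parameters of the mechanical-signalling model
#'
#' @param medium An [elastic_medium()].
#' @param sigma_th Stress threshold (Pa), > 0.
#' @param P Isotropic dipole strength (stress x area).
#' @param A Anisotropic dipole strength; with
#'   `mode = "anisotropic"` orientations are drawn at random per nucleus.
#' @param mode `"isotropic"` (A forced to 0), `"anisotropic"` (P forced to
#'   0) or `"mixed"`.
#' @param smoothing_width Gaussian regularization width of the dipoles (µm);
#'   defaults to a quarter of the nuclear spacing `d`.
#' @param d Nuclear spacing (µm).
#' @param refractory Refractory duration (s).
#' @param nu_visc Per-cycle viscosity-scaling exponent (>= 0):
#'   `D_n = D_n0 * 2^(-nu_visc (n - n0))`.
#' @return Object of class `mechanical_params`.
#' @export
mechanical_params <- function(medium, sigma_th, P = 1, A = 0,
                              mode = c("isotropic", "anisotropic", "mixed"),
                              smoothing_width = NULL, d = 1,
                              refractory = Inf, nu_visc = 0) {
  mode <- match.arg(mode)
  stop_if_not_positive(sigma_th = sigma_th, d = d)
  if (nu_visc < 0) stop("nu_visc must be >= 0")
  if (mode == "isotropic") A <- 0
  if (mode == "anisotropic") P <- 0
  if (is.null(smoothing_width)) smoothing_width <- d / 4
  structure(list(medium = medium, sigma_th = sigma_th, P = P, A = A,
                 mode = mode, smoothing_width = smoothing_width, d = d,
                 refractory = refractory, nu_visc = nu_visc),
            class = "mechanical_params")
}

#' Simulate a mechanical wavefront
#'
#' Time-steps the damped elastic field; at each step every untriggered
#' nucleus whose interpolated largest principal stress exceeds `sigma_th`
#' activates its own dipole (crossing times refined by linear interpolation
#' between steps; the new source enters the field from the following step).
#' Activations within a step are processed in (time, x, y, id) order.
#'
#' @param params A [mechanical_params()].
#' @param positions Data frame with columns `x`, `y` (µm) inside the domain.
#' @param initiation `"center"` (the nucleus nearest the domain center
#'   starts at t = 0), `"both-ends"` (the nuclei of the leftmost and
#'   rightmost columns start simultaneously) or an integer vector of
#'   initiator indices.
#' @param dt Time step (s); default `0.05 d^2 / D_t`.
#' @param max_time Simulation horizon (s).
#' @param stall_time Stop after this long without a new activation (front
#'   failed to propagate further; reported, not an error).
#' @param probe_x Optional x-stations (µm) at which the y-averaged `u_x` is
#'   recorded each step.
#' @param seed Seed for random dipole orientations.
#' @return List: `onsets` (data frame `id`, `x`, `y`, `t_on`; `NA` when
#'   never triggered), `history` (data frame `t`, `station`, `ux`, or NULL),
#'   `state` (final `displacement_state`), `propagated` (logical).
#' @export
simulate_mechanical_front <- function(params, positions,
                                      initiation = "center", dt = NULL,
                                      max_time = NULL, stall_time = NULL,
                                      probe_x = NULL, seed = 1) {
  stopifnot(inherits(params, "mechanical_params"))
  med <- params$medium
  n <- nrow(positions)
  pos <- as.matrix(positions[, c("x", "y")])
  t_d <- params$d^2 / med$D_t
  if (is.null(dt)) dt <- 0.05 * t_d
  if (is.null(max_time)) max_time <- 60 * n * t_d
  if (is.null(stall_time)) max_stall <- 30 * t_d else max_stall <- stall_time
  phis <- if (params$mode %in% c("anisotropic", "mixed"))
    with_seed(seed, stats::runif(n, 0, pi)) else rep(0, n)
  tensors <- lapply(seq_len(n), function(i)
    dipole_source_tensor(params$P, params$A, phis[i]))

  init_idx <- if (is.numeric(initiation)) as.integer(initiation)
  else if (identical(initiation, "center")) {
    ctr <- c(med$length_x / 2, med$length_y / 2)
    which.min((pos[, 1L] - ctr[1L])^2 + (pos[, 2L] - ctr[2L])^2)
  } else if (identical(initiation, "both-ends")) {
    tolx <- params$d / 2
    which(pos[, 1L] <= min(pos[, 1L]) + tolx |
            pos[, 1L] >= max(pos[, 1L]) - tolx)
  } else stop("unknown initiation")

  state <- displacement_state(med)
  t_on <- rep(NA_real_, n)
  t_on[init_idx] <- 0
  for (i in init_idx)
    state <- add_dipole(state, tensors[[i]], pos[i, ], params$smoothing_width)
  untrig <- setdiff(seq_len(n), init_idx)
  hist_rows <- list()
  prev_excess <- rep(-params$sigma_th, n)
  last_act <- 0
  # with probe stations the field keeps evolving to max_time so the
  # post-front relaxation is recorded; otherwise stop once every nucleus
  # has triggered (or the front stalls)
  while (state$time < max_time &&
         (length(untrig) > 0L || !is.null(probe_x)) &&
         (length(untrig) == 0L || state$time - last_act < max_stall)) {
    state <- evolve_displacement(state, dt)
    sf <- stress_field(state)
    lam_max <- max_principal_stress(sf$sxx, sf$syy, sf$sxy)
    if (!is.null(probe_x)) {
      fld <- displacement_field(state)
      cols <- pmin(pmax(round(probe_x / med$h) + 1L, 1L), med$nx)
      hist_rows[[length(hist_rows) + 1L]] <- data.frame(
        t = state$time, station = probe_x,
        ux = vapply(cols, function(cc) mean(fld$ux[cc, ]), numeric(1)),
        uy = vapply(cols, function(cc) mean(fld$uy[cc, ]), numeric(1)))
    }
    excess <- interp_grid(lam_max, med$h, pos[untrig, 1L],
                          pos[untrig, 2L]) - params$sigma_th
    crossed <- untrig[excess >= 0]
    if (length(crossed) > 0L) {
      # refine crossing times within the step by linear interpolation
      e1 <- excess[excess >= 0]
      e0 <- prev_excess[crossed]
      frac <- ifelse(e0 < 0, -e0 / (e1 - e0), 1)
      t_cross <- state$time - dt + pmin(pmax(frac, 0), 1) * dt
      ordc <- order(t_cross, pos[crossed, 1L], pos[crossed, 2L], crossed)
      for (k in ordc) {
        i <- crossed[k]
        t_on[i] <- t_cross[k]
        state <- add_dipole(state, tensors[[i]], pos[i, ],
                            params$smoothing_width)
      }
      last_act <- state$time
    }
    prev_excess[untrig] <- excess
    untrig <- setdiff(untrig, crossed)
  }
  history <- if (length(hist_rows) > 0L) do.call(rbind, hist_rows) else NULL
  list(onsets = data.frame(id = seq_len(n), x = pos[, 1L], y = pos[, 2L],
                           t_on = t_on),
       history = history, state = state,
       propagated = sum(!is.na(t_on)) > length(init_idx))
}

#' Measure the dimensional mechanical front speed on a periodic strip
#'
#' Nuclei sit on a square lattice of spacing `d` on a strip periodic in both
#' directions; the full leftmost column is activated at t = 0 and two
#' counter-propagating fronts emerge.  The speed is the inverse slope of the
#' per-column mean activation time vs x for the +x-going front up to just
#' before the collision point (steadiness checked on the far quarters).
#'
#' @param mu,lam,gamma Elastic moduli (Pa) and damping (Pa s / µm^2).
#' @param d Nuclear spacing (µm).
#' @param P,A Dipole strengths (stress x area).
#' @param sigma_th Stress threshold (Pa).
#' @param mode Anisotropy mode, see [mechanical_params()].
#' @param n_cols,n_rows Lattice size (columns along x, rows along y).
#' @param h_frac Grid spacing in units of `d` (default 1/8).
#' @param dt_frac Time step in units of `d^2/D_t` (default 0.01;
#'   activation-time resolution, the spectral update itself is exact).
#' @param seed Seed for anisotropic orientations.
#' @return Front speed (µm/s); 0 if the front does not propagate through
#'   the strip.
#' @export
measure_mech_front_speed <- function(mu = 1, lam = 0, gamma = 1, d = 1,
                                     P = 1, A = 0, sigma_th = 0.1,
                                     mode = "isotropic", n_cols = 32,
                                     n_rows = 4, h_frac = 0.125,
                                     dt_frac = 0.01, seed = 1) {
  med <- elastic_medium(mu = mu, lam = lam, gamma = gamma,
                        length_x = n_cols * d, length_y = n_rows * d,
                        h = h_frac * d, bc = "periodic")
  par <- mechanical_params(med, sigma_th = sigma_th, P = P, A = A,
                           mode = mode, d = d)
  lat <- expand.grid(x = seq(0, n_cols - 1) * d,
                     y = seq(0.5, n_rows - 0.5) * d)
  init <- which(lat$x == 0)
  dt <- dt_frac * d^2 / med$D_t
  sim <- simulate_mechanical_front(par, lat, initiation = init,
                                   dt = dt, seed = seed)
  on <- sim$onsets
  if (anyNA(on$t_on) || !sim$propagated) return(0)
  # refine the step once if the front crosses a column in only a few steps,
  # so activation times stay resolved for fast fronts
  interval <- stats::median(diff(sort(tapply(on$t_on, on$x, mean))))
  if (is.finite(interval) && interval < 8 * dt) {
    dt <- interval / 10
    sim <- simulate_mechanical_front(par, lat, initiation = init,
                                     dt = dt, seed = seed)
    on <- sim$onsets
    if (anyNA(on$t_on) || !sim$propagated) return(0)
  }
  tcol <- tapply(on$t_on, on$x, mean)
  xs <- as.numeric(names(tcol))
  keep <- xs >= d & xs <= (floor(n_cols / 2) - 2) * d
  xs <- xs[keep]; tc <- as.numeric(tcol)[keep]
  sel <- function(lo, hi) xs >= stats::quantile(xs, lo) &
    xs <= stats::quantile(xs, hi)
  v3 <- 1 / unname(stats::coef(stats::lm(tc[sel(0.5, 0.75)] ~
                                           xs[sel(0.5, 0.75)]))[2L])
  v4 <- 1 / unname(stats::coef(stats::lm(tc[sel(0.75, 1)] ~
                                           xs[sel(0.75, 1)]))[2L])
  if (abs(v4 - v3) > 0.05 * abs(v4))
    warning("mechanical front not steady over the far half")
  1 / unname(stats::coef(stats::lm(tc[sel(0.5, 1)] ~ xs[sel(0.5, 1)]))[2L])
}

# Session cache for mechanical speed-function evaluations.
.mech_speed_cache <- new.env(parent = emptyenv())

#' Nondimensional mechanical front speed
#'
#' Measures `v* = v d / D_t` as a function of the dimensionless threshold
#' `sigma* = sigma_th d^2 / P` (for anisotropic sources `P` is replaced by
#' the typical strength `A`), the diffusion-constant ratio `D_l/D_t` and the
#' anisotropy mode, by simulating a planar front on a periodic strip:
#' nuclei on a square lattice at unit spacing, the full leftmost column
#' activated at t = 0, speed from the least-squares slope of activation
#' time vs x over the far half of the strip (checked for steadiness).
#' Results are cached per session.
#'
#' @param sigma_star Dimensionless stress threshold, > 0.
#' @param ratio `D_l / D_t` (>= 1 for ordinary media; default 2,
#'   i.e. `lam = 0`).
#' @param mode Anisotropy mode, see [mechanical_params()].
#' @param n_cols,n_rows Lattice size (columns along x, rows along y).
#' @param h Grid spacing in units of the nuclear spacing (default 1/8).
#' @param dt_frac Time step in units of `d^2/D_t` (default 0.01;
#'   activation-time resolution, the spectral update itself is exact).
#' @param seed Seed for anisotropic orientations.
#' @return `v*` (0 when the front does not propagate).
#' @export
mech_speed_function <- function(sigma_star, ratio = 2,
                                mode = "isotropic", n_cols = 32, n_rows = 4,
                                h = 0.125, dt_frac = 0.01, seed = 1) {
  key <- paste(signif(sigma_star, 10), signif(ratio, 10), mode, n_cols,
               n_rows, h, dt_frac, seed, sep = "|")
  if (!is.null(.mech_speed_cache[[key]])) return(.mech_speed_cache[[key]])
  v <- measure_mech_front_speed(mu = 1, lam = ratio - 2, gamma = 1, d = 1,
                                P = if (mode == "anisotropic") 0 else 1,
                                A = if (mode == "isotropic") 0 else 1,
                                sigma_th = sigma_star, mode = mode,
                                n_cols = n_cols, n_rows = n_rows,
                                h_frac = h, dt_frac = dt_frac, seed = seed)
  .mech_speed_cache[[key]] <- v
  v
}

#' Mechanical-model wavefront speed per cycle
#'
#' Per-cycle prediction `v_n = (D_n / d_n) * Psi(sigma*_n)` where
#' `D_n = D_n0 * 2^(-nu_visc (n - n0))` encodes the concentration-driven
#' stiffening/damping of the cytoskeleton (filament concentration doubles
#' each cycle; `D ~ c^(-nu)`), `d_n` comes from the schedule, and
#' `sigma*_n = sigma_th d_n^2 / P`.
#'
#' @param schedule A [cycle_schedule()].
#' @param D_first Transverse displacement diffusion constant in the first
#'   cycle (µm^2/s).
#' @param nu_visc Scaling exponent (>= 0).
#' @param sigma_th,P Threshold (Pa) and dipole strength (stress x area).
#' @param ratio,mode,... Passed to [mech_speed_function()].
#' @return Data frame: `cycle`, `d`, `D`, `sigma_star`, `v_star`, `speed`.
#' @export
predict_speed_vs_cycle_mechanical <- function(schedule, D_first, nu_visc,
                                              sigma_th, P = 1, ratio = 2,
                                              mode = "isotropic", ...) {
  cycles <- schedule$cycles
  rows <- lapply(cycles, function(n) {
    d_n <- cycle_spacing(schedule, n)
    D_n <- D_first * 2^(-nu_visc * (n - schedule$first_cycle))
    s_star <- sigma_th * d_n^2 / P
    v_star <- mech_speed_function(s_star, ratio, mode, ...)
    data.frame(cycle = n, d = d_n, D = D_n, sigma_star = s_star,
               v_star = v_star, speed = v_star * D_n / d_n)
  })
  do.call(rbind, rows)
}

#' Fit the viscosity-scaling exponent to observed speeds
#'
#' In the model `v_n = (D_n0 2^(-nu (n - n0)) / d_n) Psi(sigma*_n)` the
#' dimensionless factor `Psi(sigma*_n)` does not involve `nu` or `D_n0`, so
#' on a log scale the fit is a linear regression of
#' `log v_obs - log(Psi_n / d_n)` on `(n - n0)`: least squares in relative
#' speed error, solved in closed form.
#'
#' @param observed_speeds Observed speeds (µm/s), one per cycle, >= 3 cycles.
#' @param cycles Cycle numbers.
#' @param schedule A [cycle_schedule()].
#' @param sigma_th,P,ratio,mode,... As in
#'   [predict_speed_vs_cycle_mechanical()].
#' @return List: `nu_visc`, `D_first`, `fitted` (data frame with per-cycle
#'   predictions), `resid_log` (log residuals).
#' @export
fit_nu <- function(observed_speeds, cycles, schedule, sigma_th, P = 1,
                   ratio = 2, mode = "isotropic", ...) {
  stopifnot(length(observed_speeds) >= 3L, all(observed_speeds > 0))
  d_n <- cycle_spacing(schedule, cycles)
  psi <- vapply(d_n, function(d)
    mech_speed_function(sigma_th * d^2 / P, ratio, mode, ...), numeric(1))
  if (any(psi <= 0))
    stop("front does not propagate at the given threshold for some cycle")
  m <- cycles - schedule$first_cycle
  yy <- log(observed_speeds) - log(psi / d_n)
  fit <- stats::lm(yy ~ m)
  nu <- -unname(stats::coef(fit)[2L]) / log(2)
  D0 <- exp(unname(stats::coef(fit)[1L]))
  pred <- (D0 * 2^(-nu * m) / d_n) * psi
  list(nu_visc = nu, D_first = D0,
       fitted = data.frame(cycle = cycles, d = d_n, psi = psi,
                           observed = observed_speeds, predicted = pred),
       resid_log = unname(stats::residuals(fit)))
}

#' Displacement profile at a station during a front passage
#'
#' Runs a mechanical front simulation and records the y-averaged
#' x-displacement at the requested station, the model counterpart of the
#' slice-averaged displacement response measured after metaphase onset.
#'
#' @param params A [mechanical_params()] (use `bc = "mirror_x"` for the
#'   embryo-like geometry).
#' @param positions Nucleus positions.
#' @param station_x Station (µm).
#' @param initiation See [simulate_mechanical_front()].
#' @param ... Passed to [simulate_mechanical_front()].
#' @return Data frame `t`, `ux` (µm), plus attribute `onset` (activation
#'   time of the nucleus nearest the station).
#' @export
predict_displacement_profile <- function(params, positions, station_x,
                                         initiation = "both-ends", ...) {
  sim <- simulate_mechanical_front(params, positions,
                                   initiation = initiation,
                                   probe_x = station_x, ...)
  h <- sim$history
  out <- data.frame(t = h$t, ux = h$ux, uy = h$uy)
  near <- which.min(abs(sim$onsets$x - station_x))
  attr(out, "onset") <- sim$onsets$t_on[near]
  out
}

#' Damping-constant estimate from network microstructure
#'
#' `Gamma = prefactor * c * eta / xi^2`: drag of a filament network of mesh
#' size `xi` immersed in a fluid of viscosity `eta`, proportional to the
#' filament concentration factor.
#'
#' @param eta Ambient fluid viscosity (Pa s).
#' @param concentration_factor Dimensionless filament concentration factor.
#' @param xi Mesh size (µm).
#' @param prefactor Dimensionless prefactor (default 1; configurable).
#' @return Damping constant (Pa s / µm^2).
#' @export
drag_estimate <- function(eta, concentration_factor, xi, prefactor = 1) {
  stop_if_not_positive(eta = eta,
                       concentration_factor = concentration_factor, xi = xi)
  prefactor * concentration_factor * eta / xi^2
}
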