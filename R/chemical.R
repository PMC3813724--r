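#' Parameters of the biochemical-signalling model
#'
#' A nucleus whose local concentration of the signalling species exceeds
#' `C_th` starts mitosis and, after a trigger-to-release delay `tau_d`,
#' releases a further quantity `Q` as a localized pulse that spreads by free
#' diffusion.  A refractory period (the interphase duration) prevents
#' re-triggering within a cycle.
#'
#' @param D Diffusion constant (µm^2/s).
#' @param Q Released quantity per pulse (amount; per unit thickness in 2D).
#' @param C_th Concentration threshold (amount/µm^dim).
#' @param tau_d Trigger-to-release delay (s), >= 0.
#' @param refractory Refractory duration (s), >= 0.
#' @param dim Spatial dimensionality of the diffusion kernel (2 or 3).
#' @param d Nuclear spacing (µm).
#' @return Object of class `chemical_params`.
#' @export
chemical_params <- function(D = 20, Q = 1, C_th = 5e-4, tau_d = 0,
                            refractory = 0, dim = 2, d = 10) {
  stop_if_not_positive(D = D, Q = Q, C_th = C_th, d = d)
  if (!(dim %in% c(2, 3))) stop("dim must be 2 or 3")
  if (tau_d < 0 || refractory < 0) stop("delays must be >= 0")
  structure(list(D = D, Q = Q, C_th = C_th, tau_d = tau_d,
                 refractory = refractory, dim = dim, d = d),
            class = "chemical_params")
}

#' Free-diffusion concentration from point releases
#'
#' Superposition of free-space heat kernels: a release of quantity `Q_i` at
#' position `p_i` and time `t_i` contributes
#' `Q_i (4 pi D (t - t_i))^(-dim/2) exp(-r^2 / (4 D (t - t_i)))` for
#' `t > t_i`.
#'
#' @param points Matrix (n x dim) or vector of evaluation position(s) (µm).
#' @param time Evaluation time (s).
#' @param releases Data frame with columns `x`, `y` (and `z` if `dim = 3`),
#'   `t`, `Q`.
#' @param D Diffusion constant (µm^2/s).
#' @param dim 2 or 3.
#' @return Concentration at each point; `Inf` at a release's own position
#'   and time.
#' @export
green_concentration <- function(points, time, releases, D, dim = 2) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  cols <- c("x", "y", "z")[seq_len(dim)]
  rel <- as.matrix(releases[, cols, drop = FALSE])
  dt <- time - releases$t
  out <- numeric(nrow(points))
  for (k in seq_len(nrow(rel))) {
    if (dt[k] < 0) next
    r2 <- rowSums((points - matrix(rel[k, ], nrow(points), dim,
                                   byrow = TRUE))^2)
    if (dt[k] == 0) {
      out[r2 == 0] <- Inf
      next
    }
    out <- out + releases$Q[k] * (4 * pi * D * dt[k])^(-dim / 2) *
      exp(-r2 / (4 * D * dt[k]))
  }
  out
}

# Concentration at a single point for a vector of times (vectorized over
# releases x times).
conc_series <- function(point, times, rel_pos, rel_t, rel_Q, D, dim) {
  r2 <- rowSums((rel_pos - matrix(point, nrow(rel_pos), ncol(rel_pos),
                                  byrow = TRUE))^2)
  dt <- outer(rel_t, times, function(a, b) b - a)   # releases x times
  pos <- dt > 0
  ker <- matrix(0, nrow(dt), ncol(dt))
  ker[pos] <- (4 * pi * D * dt[pos])^(-dim / 2) *
    exp(-(r2[row(dt)[pos]]) / (4 * D * dt[pos]))
  colSums(rel_Q * ker)
}

# Concentration at several points (rows of pts) at a single time.
conc_points <- function(pts, time, rel_pos, rel_t, rel_Q, D, dim) {
  dt <- time - rel_t
  act <- which(dt > 0)
  if (length(act) == 0L) return(numeric(nrow(pts)))
  out <- numeric(nrow(pts))
  for (k in act) {
    r2 <- (pts[, 1L] - rel_pos[k, 1L])^2 + (pts[, 2L] - rel_pos[k, 2L])^2
    out <- out + rel_Q[k] * (4 * pi * D * dt[k])^(-dim / 2) *
      exp(-r2 / (4 * D * dt[k]))
  }
  out
}

# Bisection refinement of a crossing inside (lo, hi] at a single point.
refine_crossing <- function(point, rel_pos, rel_t, rel_Q, D, dim, C_th,
                            lo, hi, tol) {
  pt <- matrix(point, 1L)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (conc_points(pt, mid, rel_pos, rel_t, rel_Q, D, dim)[1L] >= C_th)
      hi <- mid else lo <- mid
  }
  hi
}

#' Event-driven simulation of the chemical wavefront
#'
#' Simulates threshold-triggered releases coupled by free diffusion using
#' the analytic superposition of heat kernels (no spatial discretization).
#' The system starts with a single nucleus releasing `Q` at `t = 0`; each
#' untriggered nucleus's earliest threshold-crossing time is found by grid
#' scan plus bisection on the analytic field, the globally earliest crossing
#' is committed, and that nucleus's own release is scheduled `tau_d` later.
#' Each nucleus triggers at most once per run (the refractory period spans
#' the rest of the cycle).  Simultaneous crossings are processed in
#' (time, x, y, id) order.
#'
#' @param params A [chemical_params()].
#' @param positions Data frame with columns `x`, `y` (µm), distinct rows.
#' @param init Index of the initially releasing nucleus (default 1).
#' @param t_max Simulation horizon (s).
#' @param stall_time Stop after this long without a new trigger (front
#'   failed to propagate; the remaining nuclei stay `NA`).
#' @param cutoff Frontier radius: concentration is monitored only at nuclei
#'   within `cutoff` of some past release (in units of the spacing `d`);
#'   farther nuclei cannot cross earlier than nearer ones.
#' @return Data frame: `id`, `x`, `y`, `trigger_time`, `release_time`
#'   (`NA` for nuclei never triggered; a warning is raised if none are).
#' @export
simulate_chemical_front <- function(params, positions, init = 1L,
                                    t_max = NULL, stall_time = NULL,
                                    cutoff = 6) {
  stopifnot(inherits(params, "chemical_params"), nrow(positions) >= 2L)
  if (anyDuplicated(positions[, c("x", "y")])) stop("positions must be distinct")
  D <- params$D; dimn <- params$dim
  n <- nrow(positions)
  pos <- as.matrix(positions[, c("x", "y")])
  t_diff <- params$d^2 / D
  t_char <- max(t_diff, params$tau_d)
  if (is.null(t_max)) t_max <- 50 * n * t_char
  if (is.null(stall_time)) stall_time <- 200 * t_char
  dt_scan <- min(t_diff, if (params$tau_d > 0) params$tau_d else Inf) / 20
  tol <- 1e-3 * min(t_diff, if (params$tau_d > 0) params$tau_d else Inf)

  trigger <- rep(NA_real_, n)
  release <- rep(NA_real_, n)
  trigger[init] <- 0
  release[init] <- 0
  rel_pos <- pos[init, , drop = FALSE]
  rel_t <- 0
  rel_Q <- params$Q
  untrig <- setdiff(seq_len(n), init)
  cut2 <- (cutoff * params$d)^2
  near_frontier <- function(idx) {
    if (length(idx) == 0L) return(idx)
    keep <- vapply(idx, function(j) {
      min((pos[j, 1L] - rel_pos[, 1L])^2 +
            (pos[j, 2L] - rel_pos[, 2L])^2) <= cut2
    }, logical(1))
    idx[keep]
  }
  frontier <- near_frontier(untrig)
  t_now <- 0
  last_trig <- 0
  trig_times <- 0
  while (length(untrig) > 0L && t_now < t_max &&
         t_now - last_trig < stall_time) {
    # adapt the scan step to the recent trigger rate so that crossing
    # brackets stay small compared with the inter-trigger interval
    nt <- length(trig_times)
    dt_cur <- if (nt >= 3L)
      min(dt_scan, max((trig_times[nt] - trig_times[nt - 2L]) / 8,
                       4 * tol))
    else dt_scan
    t_next <- t_now + dt_cur
    cc <- conc_points(pos[frontier, , drop = FALSE], t_next, rel_pos,
                      rel_t, rel_Q, D, dimn)
    hit <- frontier[cc >= params$C_th]
    if (length(hit) > 0L) {
      t_cross <- vapply(hit, function(j)
        refine_crossing(pos[j, ], rel_pos, rel_t, rel_Q, D, dimn,
                        params$C_th, t_now, t_next, tol), numeric(1))
      ordc <- order(t_cross, pos[hit, 1L], pos[hit, 2L], hit)
      for (k in ordc) {
        j <- hit[k]
        trigger[j] <- t_cross[k]
        release[j] <- t_cross[k] + params$tau_d
        rel_pos <- rbind(rel_pos, pos[j, ])
        rel_t <- c(rel_t, release[j])
        rel_Q <- c(rel_Q, params$Q)
      }
      untrig <- setdiff(untrig, hit)
      frontier <- near_frontier(untrig)
      last_trig <- t_next
      trig_times <- c(trig_times, sort(t_cross))
    }
    t_now <- t_next
  }
  if (all(is.na(trigger[-init]))) warning("no nucleus was ever triggered")
  data.frame(id = seq_len(n), x = pos[, 1L], y = pos[, 2L],
             trigger_time = trigger, release_time = release)
}

#' Nondimensional threshold
#'
#' `C* = C_th d^dim / Q`: the threshold concentration measured in units of
#' one released quantity spread over one nuclear-spacing volume.  In three
#' dimensions the power of the spacing is 3.
#'
#' @param C_th Threshold (amount/µm^dim).
#' @param d Nuclear spacing (µm).
#' @param Q Released quantity.
#' @param dim 2 or 3.
#' @return Dimensionless threshold.
#' @export
nondim_threshold <- function(C_th, d, Q, dim = 2) {
  stop_if_not_positive(C_th = C_th, d = d, Q = Q)
  if (!(dim %in% c(2, 3))) stop("dim must be 2 or 3")
  C_th * d^dim / Q
}

#' Nondimensional speed and its inverse
#'
#' `v* = v d / D`; the dimensional speed is `v = v* D / d`.
#'
#' @param v Front speed (µm/s).
#' @param d Nuclear spacing (µm).
#' @param D Diffusion constant (µm^2/s).
#' @return Dimensionless speed.
#' @export
nondim_speed <- function(v, d, D) {
  stop_if_not_positive(v = v, d = d, D = D)
  v * d / D
}

#' @rdname nondim_speed
#' @param v_star Dimensionless speed.
#' @export
dim_speed <- function(v_star, d, D) v_star * D / d

#' Measure the dimensional chemical front speed on a chain
#'
#' Simulates the event-driven front along a 1D chain of `n_nuclei` nuclei at
#' spacing `params$d` (first nucleus releasing at t = 0) and returns the
#' asymptotic front speed: the inverse slope of release time vs position
#' over the far half of the chain.  Steadiness is checked by comparing the
#' third- and fourth-quarter speeds (warning if they differ by more than
#' 5%).
#'
#' @param params A [chemical_params()].
#' @param n_nuclei Chain length.
#' @return Front speed (µm/s); 0 if the front fails to reach the chain end.
#' @export
measure_chem_front_speed <- function(params, n_nuclei = 40) {
  chain <- data.frame(x = (0:(n_nuclei - 1L)) * params$d, y = 0)
  sim <- simulate_chemical_front(params, chain, init = 1L)
  if (anyNA(sim$release_time)) return(0)
  xend <- max(sim$x)
  far <- sim[sim$x >= xend / 2, ]
  q3 <- sim[sim$x >= 0.5 * xend & sim$x < 0.75 * xend, ]
  q4 <- sim[sim$x >= 0.75 * xend, ]
  v3 <- 1 / unname(stats::coef(stats::lm(release_time ~ x, q3))[2L])
  v4 <- 1 / unname(stats::coef(stats::lm(release_time ~ x, q4))[2L])
  if (abs(v4 - v3) > 0.05 * abs(v4))
    warning("front not steady over the last half of the chain")
  1 / unname(stats::coef(stats::lm(release_time ~ x, far))[2L])
}

# Session cache for chemical speed-function evaluations.
.chem_speed_cache <- new.env(parent = emptyenv())

#' Nondimensional chemical front speed
#'
#' Measures the steady-state dimensionless front speed `v*(C*, tau*)` by
#' event-driven simulation of a 1D chain of nuclei at unit spacing and unit
#' diffusion constant (so dimensional and dimensionless quantities
#' coincide).  The speed is the least-squares slope of release position vs
#' time over the far half of the chain; steadiness is checked by comparing
#' the third- and fourth-quarter speeds.  Results are cached per session.
#'
#' @param C_star Dimensionless threshold, > 0.
#' @param tau_star Dimensionless delay `tau_d D / d^2`, >= 0.
#' @param n_nuclei Chain length (default 40).
#' @param dim Kernel dimensionality (default 2).
#' @return `v*` (0 when the front fails to propagate down the chain).
#' @export
chem_speed_function <- function(C_star, tau_star = 0, n_nuclei = 40,
                                dim = 2) {
  key <- paste(signif(C_star, 10), signif(tau_star, 10), n_nuclei, dim,
               sep = "|")
  if (!is.null(.chem_speed_cache[[key]])) return(.chem_speed_cache[[key]])
  p <- chemical_params(D = 1, Q = 1, C_th = C_star, tau_d = tau_star,
                       dim = dim, d = 1)
  v <- measure_chem_front_speed(p, n_nuclei)
  .chem_speed_cache[[key]] <- v
  v
}

#' Modified Stokes-Einstein diffusion constant
#'
#' `D = k_B T / (6 pi eta R) * correction(R)`; the multiplicative correction
#' accounts for the crowded cytoplasm and defaults to identity.
#'
#' @param radius_nm Hydrodynamic radius (nm).
#' @param temperature Temperature (K).
#' @param viscosity Dynamic viscosity (Pa s); default water at 25 C.
#' @param correction Function of the radius (nm) returning a dimensionless
#'   factor.
#' @return Diffusion constant (µm^2/s).
#' @export
stokes_einstein <- function(radius_nm, temperature = 298,
                            viscosity = 0.89e-3,
                            correction = function(R) 1) {
  stop_if_not_positive(radius_nm = radius_nm, temperature = temperature,
                       viscosity = viscosity)
  kB <- 1.380649e-23
  D_m2s <- kB * temperature / (6 * pi * viscosity * radius_nm * 1e-9)
  D_m2s * 1e12 * correction(radius_nm)
}

#' Chemical-model wavefront speed per cycle
#'
#' With fixed `(D, C_th, Q)` and halving nuclear density, the dimensionless
#' threshold `C* = C_th d^dim / Q` falls each cycle while the velocity scale
#' `D/d` rises, so the zero-delay front speed increases with cycle — the
#' opposite of the observed slowing.  A delay caps the speed at `d/tau_d`,
#' which decreases with cycle; a small fixed delay therefore produces a
#' rise-then-level-off crossover.
#'
#' @param params A [chemical_params()] (its `d` is ignored; the schedule
#'   supplies spacings).
#' @param schedule A [cycle_schedule()].
#' @param delay_mode `"zero"`, `"fixed"` (use `params$tau_d`), or
#'   `"per-cycle"` (supply `tau_by_cycle`).
#' @param tau_by_cycle Optional vector of delays (s), one per cycle.
#' @param n_nuclei Chain length for the underlying speed measurements.
#' @return Data frame: `cycle`, `d`, `C_star`, `tau_star`, `v_star`,
#'   `speed` (µm/s).
#' @export
predict_speed_vs_cycle_chemical <- function(params, schedule,
                                            delay_mode = c("zero", "fixed",
                                                           "per-cycle"),
                                            tau_by_cycle = NULL,
                                            n_nuclei = 40) {
  delay_mode <- match.arg(delay_mode)
  cycles <- schedule$cycles
  tau <- switch(delay_mode,
                zero = rep(0, length(cycles)),
                fixed = rep(params$tau_d, length(cycles)),
                `per-cycle` = {
                  stopifnot(length(tau_by_cycle) == length(cycles))
                  tau_by_cycle
                })
  rows <- lapply(seq_along(cycles), function(i) {
    d_n <- cycle_spacing(schedule, cycles[i])
    C_star <- nondim_threshold(params$C_th, d_n, params$Q, params$dim)
    tau_star <- tau[i] * params$D / d_n^2
    v_star <- chem_speed_function(C_star, tau_star, n_nuclei, params$dim)
    data.frame(cycle = cycles[i], d = d_n, C_star = C_star,
               tau_star = tau_star, v_star = v_star,
               speed = dim_speed(v_star, d_n, params$D))
  })
  do.call(rbind, rows)
}

#' Fit a per-cycle delay to observed speeds
#'
#' For each cycle, finds by bisection the delay `tau_d` at which the
#' simulated chemical front speed matches the observed speed to 0.5%.
#' Observed speeds above the zero-delay speed are infeasible (a delay can
#' only slow the front).
#'
#' @param observed_speeds Observed wavefront speeds (µm/s), one per cycle.
#' @param cycles Cycle numbers.
#' @param params A [chemical_params()].
#' @param schedule A [cycle_schedule()].
#' @param n_nuclei Chain length for the speed measurements.
#' @return Data frame: `cycle`, `observed`, `v_zero_delay`, `tau_d`
#'   (`NA` with `feasible = FALSE` when unmatchable).
#' @export
fit_delay_per_cycle <- function(observed_speeds, cycles, params, schedule,
                                n_nuclei = 40) {
  stopifnot(all(observed_speeds > 0), length(observed_speeds) ==
              length(cycles))
  rows <- lapply(seq_along(cycles), function(i) {
    d_n <- cycle_spacing(schedule, cycles[i])
    C_star <- nondim_threshold(params$C_th, d_n, params$Q, params$dim)
    speed_at <- function(tau) {
      tau_star <- tau * params$D / d_n^2
      dim_speed(chem_speed_function(C_star, tau_star, n_nuclei, params$dim),
                d_n, params$D)
    }
    v0 <- speed_at(0)
    v_obs <- observed_speeds[i]
    if (v_obs > v0)
      return(data.frame(cycle = cycles[i], observed = v_obs,
                        v_zero_delay = v0, tau_d = NA_real_,
                        feasible = FALSE))
    hi <- d_n^2 / params$D
    while (speed_at(hi) > v_obs) hi <- hi * 2
    lo <- 0
    repeat {
      mid <- (lo + hi) / 2
      vm <- speed_at(mid)
      if (abs(vm - v_obs) <= 0.005 * v_obs || (hi - lo) < 1e-9 * hi) break
      if (vm > v_obs) lo <- mid else hi <- mid
    }
    data.frame(cycle = cycles[i], observed = v_obs, v_zero_delay = v0,
               tau_d = mid, feasible = TRUE)
  })
  do.call(rbind, rows)
}
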