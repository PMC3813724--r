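# Least-squares line t(x) for one front; onset time is the noisy coordinate,
# so time is regressed on position and speed = |1/slope|.
fit_front_line <- function(x, t, pole) {
  n <- length(x)
  fit <- stats::lm.fit(cbind(1, x), t)
  slope <- fit$coefficients[2L]
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / max(n - 2L, 1L)
  sxx <- sum((x - mean(x))^2)
  se_slope <- if (sxx > 0) sqrt(sigma2 / sxx) else NA_real_
  speed <- 1 / abs(slope)
  list(pole = pole, speed = unname(speed),
       speed_se = unname(se_slope / slope^2),
       intercept = unname(fit$coefficients[1L]),
       slope = unname(slope), n = n,
       resid_sd = sqrt(sigma2), rss = rss)
}

empty_front <- function(pole) {
  list(pole = pole, speed = NA_real_, speed_se = NA_real_,
       intercept = NA_real_, slope = NA_real_, n = 0L,
       resid_sd = NA_real_, rss = 0)
}

#' Fit two pole wavefronts to onset events
#'
#' Onset events in one cycle form two straight lines in the x-t plane, one
#' front coming in from each pole.  The fit searches exhaustively over
#' candidate split coordinates (the event x-values between the 10th and 90th
#' quantiles), fits a least-squares line `t(x)` on each side, and keeps the
#' split minimising the total squared residual.  The front speed is
#' `|1/slope|`.
#'
#' @param events Data frame with columns `x_um` and `t_s`.
#' @param min_events Minimum events per front to report a speed (default 5).
#' @param n_boot Optional number of seeded bootstrap resamples for speed
#'   uncertainties (0 disables).
#' @param seed Seed for the bootstrap.
#' @return A list of class `front_fits`: `left`, `right` (each with `pole`,
#'   `speed` µm/s, `speed_se`, `intercept` s, `n`, `resid_sd`,
#'   optionally `speed_se_boot`), and `split` (x-coordinate used).  With
#'   fewer than `min_events` on one side (e.g. single-front data) that side
#'   is returned empty, with a warning.
#' @export
fit_two_fronts <- function(events, min_events = 5, n_boot = 0, seed = 1) {
  stopifnot(nrow(events) >= 2L * min_events || nrow(events) >= min_events)
  x <- events$x_um; t <- events$t_s
  qs <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
  cands <- sort(unique(x[x >= qs[1] & x <= qs[2]]))
  best <- NULL
  for (s in cands) {
    li <- which(x <= s); ri <- which(x > s)
    if (length(li) < min_events || length(ri) < min_events) next
    fl <- fit_front_line(x[li], t[li], "left")
    fr <- fit_front_line(x[ri], t[ri], "right")
    tot <- fl$rss + fr$rss
    if (is.null(best) || tot < best$tot)
      best <- list(left = fl, right = fr, split = s, tot = tot,
                   li = li, ri = ri)
  }
  # a genuine two-pole pattern has opposite slope signs (one front moving
  # in +x, one in -x); equal signs mean the events form a single front
  single <- is.null(best) ||
    sign(best$left$slope) == sign(best$right$slope)
  if (single) {
    warning("events form a single front; second front returned empty")
    f <- fit_front_line(x, t, if (f_sign(x, t) >= 0) "left" else "right")
    out <- if (f$pole == "left") list(left = f, right = empty_front("right"))
           else list(left = empty_front("left"), right = f)
    out$split <- NA_real_
    class(out) <- "front_fits"
    return(out)
  }
  out <- list(left = best$left, right = best$right, split = best$split)
  if (n_boot > 0) {
    bs <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        ii <- sample(best$li, replace = TRUE)
        jj <- sample(best$ri, replace = TRUE)
        c(fit_front_line(x[ii], t[ii], "left")$speed,
          fit_front_line(x[jj], t[jj], "right")$speed)
      }, numeric(2))
    })
    out$left$speed_se_boot <- stats::sd(bs[1L, ])
    out$right$speed_se_boot <- stats::sd(bs[2L, ])
  }
  class(out) <- "front_fits"
  out
}

# Sign of dt/dx: positive means a front moving in +x (left pole).
f_sign <- function(x, t) sign(stats::cov(x, t))

# R^2 without summary.lm's essentially-perfect-fit warning.
r_squared_lm <- function(fit, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / tss
}

#' Ratio of anaphase to metaphase wavefront speeds
#'
#' For a given embryo and cycle the two onset markers ride the same front,
#' so their fitted speeds should agree (ratio 1 within fit error).
#'
#' @param anaphase_fits,metaphase_fits `front_fits` objects for the same
#'   cycle.
#' @return Data frame with one row per pole: `pole`, `ratio`
#'   (`v_ana / v_meta`), `se` (propagated standard error).  Poles missing a
#'   counterpart are skipped.
#' @export
front_speed_ratio <- function(anaphase_fits, metaphase_fits) {
  rows <- lapply(c("left", "right"), function(p) {
    fa <- anaphase_fits[[p]]; fm <- metaphase_fits[[p]]
    if (fa$n == 0L || fm$n == 0L || !is.finite(fa$speed) ||
        !is.finite(fm$speed)) return(NULL)
    ratio <- fa$speed / fm$speed
    rel <- sqrt((fa$speed_se / fa$speed)^2 + (fm$speed_se / fm$speed)^2)
    data.frame(pole = p, ratio = ratio, se = ratio * rel)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(pole = character(0), ratio = numeric(0),
                      se = numeric(0)))
  do.call(rbind, rows)
}

#' Per-cycle exponential decay of the wavefront speed
#'
#' Fits `log v` linearly against the cycle number; the per-cycle factor
#' `s = v_(n+1)/v_n = exp(slope)`.
#'
#' @param speeds Positive wavefront speeds (µm/s).
#' @param cycles Cycle numbers (same length).
#' @return List: `factor` (per-cycle ratio), `v_first` (fitted speed at the
#'   first cycle), `slope`, `r_squared`.
#' @export
fit_speed_decay <- function(speeds, cycles) {
  if (any(speeds <= 0)) stop("speeds must be positive")
  stopifnot(length(unique(cycles)) >= 3L)
  fit <- stats::lm(log(speeds) ~ cycles)
  slope <- unname(stats::coef(fit)[2L])
  list(factor = exp(slope),
       v_first = exp(unname(stats::predict(
         fit, data.frame(cycles = min(cycles))))),
       slope = slope,
       r_squared = r_squared_lm(fit, log(speeds)))
}

#' Mean nearest-neighbour distance
#'
#' @param positions Data frame with columns `x`, `y` (µm); at least 2 rows,
#'   no duplicated positions.
#' @return Mean over nuclei of the distance to the nearest other nucleus
#'   (µm); boundary nuclei included.
#' @export
nn_spacing <- function(positions) {
  stopifnot(nrow(positions) >= 2L)
  if (anyDuplicated(positions[, c("x", "y")]))
    stop("duplicate positions")
  d <- as.matrix(stats::dist(positions[, c("x", "y")]))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

#' Fit the spacing decay exponent
#'
#' The spacing decays as `d_n = d_n0 * 2^(-(n - n0)/nu)`; the fit regresses
#' `log2 d` on `n` and reports `nu = -1/slope`.
#'
#' @param d Nearest-neighbour spacings (µm), one per cycle.
#' @param cycles Cycle numbers.
#' @return List: `nu` (`Inf` when the spacing does not decay), `slope`,
#'   `d_first`.  A positive slope (increasing spacing) triggers a warning.
#' @export
fit_spacing_law <- function(d, cycles) {
  stopifnot(length(unique(cycles)) >= 3L, all(d > 0))
  fit <- stats::lm(log2(d) ~ cycles)
  slope <- unname(stats::coef(fit)[2L])
  if (slope > 0) warning("spacing increases with cycle (positive slope)")
  nu <- if (abs(slope) < 1e-12) Inf else -1 / slope
  list(nu = nu, slope = slope,
       d_first = 2^unname(stats::predict(
         fit, data.frame(cycles = min(cycles)))))
}

#' Fit the exponential growth of cycle durations
#'
#' @param durations Cycle durations (s), positive.
#' @param cycles Cycle numbers.
#' @return List: `rate` (per-cycle log growth), `T_first`, `r_squared`.
#' @export
fit_cycle_durations <- function(durations, cycles) {
  if (any(durations <= 0)) stop("durations must be positive")
  stopifnot(length(unique(cycles)) >= 3L)
  fit <- stats::lm(log(durations) ~ cycles)
  list(rate = unname(stats::coef(fit)[2L]),
       T_first = exp(unname(stats::predict(
         fit, data.frame(cycles = min(cycles))))),
       r_squared = r_squared_lm(fit, log(durations)))
}

#' Per-cycle front fits from an onset-event table
#'
#' Convenience wrapper: fits the two-front model separately for each cycle
#' (and marker, if present) in an event table.
#'
#' @param events Data frame with `x_um`, `t_s`, `cycle` and optionally
#'   `marker`.
#' @param ... Passed to [fit_two_fronts()].
#' @return Data frame with one row per (cycle, marker, pole): `cycle`,
#'   `marker`, `pole`, `speed`, `speed_se`, `intercept`, `n`, `resid_sd`.
#' @export
fit_fronts_by_cycle <- function(events, ...) {
  if (is.null(events$marker)) events$marker <- "onset"
  groups <- split(events, list(events$cycle, events$marker), drop = TRUE)
  rows <- lapply(groups, function(g) {
    ff <- fit_two_fronts(g, ...)
    do.call(rbind, lapply(c("left", "right"), function(p) {
      f <- ff[[p]]
      data.frame(cycle = g$cycle[1L], marker = g$marker[1L], pole = p,
                 speed = f$speed, speed_se = f$speed_se,
                 intercept = f$intercept, n = f$n, resid_sd = f$resid_sd)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cycle, out$marker, out$pole), ]
}
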