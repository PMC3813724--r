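# Brute-force oracles used only to cross-check the package's simulators.

# Explicit finite-difference diffusion solver on a fine 2D grid for the
# threshold-triggered release model: releases are stamped as narrow
# normalized Gaussians (sd sigma_r), the field diffuses by FTCS with
# insulating edges, and each untriggered nucleus triggers when the
# bilinearly sampled concentration crosses C_th (crossing time refined by
# linear interpolation between steps).  Zero trigger-to-release delay.
chem_grid_oracle <- function(positions, D, Q, C_th, sigma_r = 0.06,
                             h = 0.06, dt = NULL, t_end = 5, pad = 3,
                             init = 1L) {
  if (is.null(dt)) dt <- 0.2 * h^2 / D
  x0 <- min(positions$x) - pad; x1 <- max(positions$x) + pad
  y0 <- min(positions$y) - pad; y1 <- max(positions$y) + pad
  nx <- ceiling((x1 - x0) / h); ny <- ceiling((y1 - y0) / h)
  xg <- x0 + (seq_len(nx) - 0.5) * h
  yg <- y0 + (seq_len(ny) - 0.5) * h
  field <- matrix(0, nx, ny)
  stamp <- function(field, px, py) {
    g <- outer(exp(-(xg - px)^2 / (2 * sigma_r^2)),
               exp(-(yg - py)^2 / (2 * sigma_r^2)))
    field + Q * g / (sum(g) * h^2)
  }
  sample_at <- function(field, px, py) {
    gx <- (px - x0) / h + 0.5; gy <- (py - y0) / h + 0.5
    i0 <- pmin(pmax(floor(gx), 1), nx - 1); j0 <- pmin(pmax(floor(gy), 1),
                                                       ny - 1)
    fx <- gx - i0; fy <- gy - j0
    field[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
      field[cbind(i0 + 1, j0)] * fx * (1 - fy) +
      field[cbind(i0, j0 + 1)] * (1 - fx) * fy +
      field[cbind(i0 + 1, j0 + 1)] * fx * fy
  }
  lap <- function(f) {
    up <- f[c(1, seq_len(nx - 1)), ]; dn <- f[c(seq_len(nx - 1) + 1, nx), ]
    lf <- f[, c(1, seq_len(ny - 1))]; rt <- f[, c(seq_len(ny - 1) + 1, ny)]
    (up + dn + lf + rt - 4 * f) / h^2
  }
  n <- nrow(positions)
  trig <- rep(NA_real_, n)
  trig[init] <- 0
  field <- stamp(field, positions$x[init], positions$y[init])
  prev <- rep(0, n)
  t <- 0
  while (t < t_end && anyNA(trig)) {
    field <- field + dt * D * lap(field)
    t <- t + dt
    cur <- sample_at(field, positions$x, positions$y)
    for (j in which(is.na(trig))) {
      if (cur[j] >= C_th) {
        frac <- if (cur[j] > prev[j])
          (C_th - prev[j]) / (cur[j] - prev[j]) else 1
        trig[j] <- t - dt + max(min(frac, 1), 0) * dt
        field <- stamp(field, positions$x[j], positions$y[j])
      }
    }
    prev <- cur
  }
  trig
}
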