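#' Bandpass filter a frame
#'
#' Difference-of-Gaussians filter: suppresses pixel noise below `low_sigma`
#' and background variation above `high_sigma`, the standard preprocessing
#' before contour detection of fluorescent nuclei.
#'
#' @param frame Numeric matrix (row 1 = top of the image).
#' @param low_sigma,high_sigma Gaussian widths in pixels,
#'   `0 < low_sigma < high_sigma`.
#' @return Filtered matrix of the same size (mean approximately zero).
#' @export
bandpass <- function(frame, low_sigma = 1, high_sigma = 8) {
  if (!all(is.finite(frame))) stop("frame contains non-finite pixels")
  stopifnot(low_sigma > 0, low_sigma < high_sigma)
  # keep the Gaussian brush smaller than the frame
  rad <- function(s) {
    r <- 2 * ceiling(3 * s) + 1
    lim <- min(dim(frame)) - 1
    if (lim %% 2 == 0) lim <- lim - 1
    min(r, lim)
  }
  lo <- EBImage::gblur(frame, sigma = low_sigma, radius = rad(low_sigma))
  hi <- EBImage::gblur(frame, sigma = high_sigma, radius = rad(high_sigma))
  as.matrix(lo - hi)
}

# Vectorized even-odd point-in-polygon test.
points_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]; xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polygon_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse (Fitzgibbon-style direct fit,
#' in the numerically stable split formulation) to a closed contour and
#' converts it to geometric parameters.
#'
#' @param x,y Coordinates of at least 5 distinct contour points.
#' @return A list with `center` (length 2), `a` (semi-major), `b`
#'   (semi-minor), `theta` (major-axis angle in `[0, pi)`; 0 when `a == b`).
#' @export
fit_ellipse <- function(x, y) {
  keep <- !duplicated(cbind(x, y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5L) stop("ellipse fit needs >= 5 distinct points")
  mx <- mean(x); my <- mean(y); sc <- max(stats::sd(x), stats::sd(y))
  if (!is.finite(sc) || sc == 0) stop("degenerate contour: zero extent")
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate contour: ellipse fit failed"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ev <- eigen(M)
  vec <- Re(ev$vectors)
  cond <- 4 * vec[1L, ] * vec[3L, ] - vec[2L, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) stop("degenerate contour: no ellipse solution")
  a1 <- vec[, ok[1L]]
  coef <- c(a1, Tm %*% a1)       # A x^2 + B xy + C y^2 + D x + E y + F (scaled)
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- 4 * A * C - B^2
  x0 <- (B * E - 2 * C * D) / den
  y0 <- (B * D - 2 * A * E) / den
  F0 <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F
  Am <- matrix(c(A, B / 2, B / 2, C), 2L)
  ed <- eigen(Am, symmetric = TRUE)
  ax2 <- -F0 / ed$values
  if (any(ax2 <= 0)) stop("degenerate contour: non-elliptical fit")
  semi <- sqrt(ax2)               # ordered: values decreasing -> semi increasing
  imaj <- which.max(semi)
  a <- semi[imaj]; b <- semi[-imaj]
  theta <- if (abs(a - b) < 1e-9 * a) 0
           else wrap_axial(atan2(ed$vectors[2L, imaj], ed$vectors[1L, imaj]))
  list(center = c(x0 * sc + mx, y0 * sc + my),
       a = a * sc, b = b * sc, theta = theta)
}

# Closed contour lines of `img` at `levels`, in pixel-center coordinates
# (x = column, y = row counted from the bottom, both in px units).
closed_contours <- function(img, levels) {
  ny <- nrow(img); nx <- ncol(img)
  cl <- grDevices::contourLines(x = seq_len(nx) - 0.5,
                                y = seq_len(ny) - 0.5,
                                z = t(img[ny:1, , drop = FALSE]),
                                levels = levels)
  keep <- vapply(cl, function(ct) {
    n <- length(ct$x)
    n >= 5L &&
      sqrt((ct$x[1] - ct$x[n])^2 + (ct$y[1] - ct$y[n])^2) < 1.5
  }, logical(1))
  cl[keep]
}

#' Detect nuclei as ellipses in one frame
#'
#' Builds a multi-level contour representation of the frame, keeps the
#' locally highest-level closed contours (those with no other closed contour
#' inside them) as nucleus seeds, and for each seed re-extracts the closed
#' contour at half-height — midway between the region's peak and its local
#' background (median intensity on a surrounding ring) — and fits it with an
#' ellipse.
#'
#' @param frame Numeric matrix (row 1 = top).
#' @param pixel_size µm per pixel.
#' @param n_levels Number of equally spaced contour levels between the 1st
#'   and 99th intensity percentiles (>= 4).
#' @param min_area Minimum area (px^2) of the half-height contour.
#' @param prominence_frac Minimum peak prominence over the local background,
#'   as a fraction of the frame's 1st-99th percentile intensity range;
#'   rejects spurious seeds from background regions and noise.
#' @param merge_dist Seeds closer than this (px) are merged, keeping the
#'   higher-level one.
#' @param win_radius Half-size (px) of the local window used to measure the
#'   region peak, its background ring, and the half-height contour; should
#'   exceed the largest expected nuclear radius.
#' @return A data frame with one row per detection: `x`, `y` (µm, y up from
#'   the bottom edge), `a`, `b` (µm), `theta` (radians in `[0, pi)`), `peak`,
#'   `level` (the half-height level used).
#' @export
detect_ellipses <- function(frame, pixel_size = 1, n_levels = 16,
                            min_area = 4, prominence_frac = 0.2,
                            merge_dist = 2, win_radius = 12) {
  if (!all(is.finite(frame))) stop("frame contains non-finite pixels")
  stopifnot(n_levels >= 4L)
  qs <- stats::quantile(frame, c(0.01, 0.99), names = FALSE)
  empty <- data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                      b = numeric(0), theta = numeric(0), peak = numeric(0),
                      level = numeric(0))
  if (qs[2] - qs[1] <= .Machine$double.eps * max(abs(qs), 1)) return(empty)
  levels <- seq(qs[1], qs[2], length.out = n_levels + 2L)[-c(1L, n_levels + 2L)]
  cc <- closed_contours(frame, levels)
  if (length(cc) == 0L) return(empty)

  bb <- t(vapply(cc, function(ct)
    c(min(ct$x), max(ct$x), min(ct$y), max(ct$y)), numeric(4)))
  n <- length(cc)
  innermost <- rep(TRUE, n)
  for (i in seq_len(n)) {
    # does any other closed contour lie strictly inside contour i?
    cand <- which(bb[, 1] >= bb[i, 1] & bb[, 2] <= bb[i, 2] &
                    bb[, 3] >= bb[i, 3] & bb[, 4] <= bb[i, 4])
    cand <- setdiff(cand, i)
    for (j in cand) {
      if (points_in_polygon(cc[[j]]$x[1], cc[[j]]$y[1],
                            cc[[i]]$x, cc[[i]]$y)) {
        innermost[i] <- FALSE
        break
      }
    }
  }
  idx <- which(innermost)
  if (length(idx) == 0L) return(empty)
  seeds <- t(vapply(idx, function(i)
    c(mean(cc[[i]]$x), mean(cc[[i]]$y), cc[[i]]$level), numeric(3)))
  # merge near-duplicate seeds, keeping the higher level
  ord <- order(-seeds[, 3L])
  seeds <- seeds[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    if (!keep[i]) next
    if (i < nrow(seeds)) {
      later <- (i + 1L):nrow(seeds)
      d2 <- (seeds[later, 1L] - seeds[i, 1L])^2 +
        (seeds[later, 2L] - seeds[i, 2L])^2
      keep[later[d2 < merge_dist^2]] <- FALSE
    }
  }
  seeds <- seeds[keep, , drop = FALSE]

  ny <- nrow(frame); nx <- ncol(frame)
  dets <- lapply(seq_len(nrow(seeds)), function(s) {
    sx <- seeds[s, 1L]; sy <- seeds[s, 2L]
    win <- function(rad) {
      c1 <- max(1L, floor(sx - rad)); c2 <- min(nx, ceiling(sx + rad))
      r1 <- max(1L, floor(ny - sy - rad)); r2 <- min(ny, ceiling(ny - sy + rad))
      list(c1 = c1, c2 = c2, r1 = r1, r2 = r2)
    }
    # region peak: maximum close to the seed (the innermost contour sits at
    # the local maximum)
    w0 <- win(max(3, win_radius / 4))
    peak <- max(frame[w0$r1:w0$r2, w0$c1:w0$c2, drop = FALSE])
    # local background: median on a ring just inside the search window
    wg <- win(win_radius)
    pg <- frame[wg$r1:wg$r2, wg$c1:wg$c2, drop = FALSE]
    cx <- (wg$c1:wg$c2) - 0.5
    cy <- ny - ((wg$r1:wg$r2) - 0.5)
    dist <- sqrt(outer((cy - sy)^2, (cx - sx)^2, `+`))
    ring <- pg[dist >= 0.7 * win_radius & dist <= win_radius]
    bg <- if (length(ring) > 0) stats::median(ring) else qs[1]
    if (peak - bg < prominence_frac * (qs[2] - qs[1])) return(NULL)
    half <- (peak + bg) / 2
    # closed contour at half-height around the seed, from the cropped window
    wh <- wg
    sub <- pg
    ctr <- closed_contours(sub, half)
    hit <- NULL
    for (ct in ctr) {
      cxs <- ct$x + (wh$c1 - 1L)
      cys <- ct$y + (ny - wh$r2)
      if (points_in_polygon(sx, sy, cxs, cys)) {
        hit <- list(x = cxs, y = cys)
        break
      }
    }
    if (is.null(hit)) return(NULL)
    if (polygon_area(hit$x, hit$y) < min_area) return(NULL)
    fit <- tryCatch(fit_ellipse(hit$x, hit$y), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(x = fit$center[1L] * pixel_size,
               y = fit$center[2L] * pixel_size,
               a = fit$a * pixel_size, b = fit$b * pixel_size,
               theta = fit$theta, peak = peak, level = half)
  })
  dets <- dets[!vapply(dets, is.null, logical(1))]
  if (length(dets) == 0L) return(empty)
  out <- do.call(rbind, dets)
  # two seeds can land inside one (merged) half-height contour; keep one
  # detection per fitted center
  if (nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (i in 2:nrow(out)) {
      d2 <- (out$x[seq_len(i - 1L)] - out$x[i])^2 +
        (out$y[seq_len(i - 1L)] - out$y[i])^2
      if (any(d2[keep[seq_len(i - 1L)]] < (merge_dist * pixel_size)^2))
        keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
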