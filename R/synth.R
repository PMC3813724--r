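#' Place nuclei on a jittered triangular lattice
#'
#' Surface nuclei in a given cycle sit at a well-defined nearest-neighbour
#' spacing; a triangular (hexagonal-packing) lattice makes that spacing
#' single-valued.  Positions are jittered uniformly within
#' `jitter_frac * d_n` in each coordinate.
#'
#' @param geometry An [embryo_geometry()].
#' @param schedule A [cycle_schedule()].
#' @param cycle Cycle number (must belong to `schedule$cycles`).
#' @param jitter_frac Jitter amplitude as a fraction of the spacing,
#'   in `[0, 0.5)`.
#' @param seed Integer seed; identical seeds give identical positions.
#' @return A data frame with columns `x`, `y` (µm) and attribute `spacing`.
#' @export
place_nuclei <- function(geometry, schedule, cycle, jitter_frac = 0.1,
                         seed = 1) {
  stopifnot(inherits(geometry, "embryo_geometry"),
            inherits(schedule, "cycle_schedule"),
            cycle %in% schedule$cycles,
            jitter_frac >= 0, jitter_frac < 0.5)
  d <- cycle_spacing(schedule, cycle)
  margin <- d / 2
  if (geometry$length_x < 2 * margin || geometry$width_y < 2 * margin)
    stop("embryo geometry too small for one lattice cell at spacing ", d)
  xs0 <- seq(margin, geometry$length_x - margin, by = d)
  ys0 <- seq(margin, geometry$width_y - margin, by = d * sqrt(3) / 2)
  pos <- do.call(rbind, lapply(seq_along(ys0), function(j) {
    xr <- xs0 + if (j %% 2L == 0L) d / 2 else 0
    xr <- xr[xr <= geometry$length_x - margin]
    cbind(x = xr, y = rep(ys0[j], length(xr)))
  }))
  if (jitter_frac > 0) {
    pos <- with_seed(seed, {
      pos + matrix(stats::runif(length(pos), -jitter_frac * d,
                                jitter_frac * d), ncol = 2L)
    })
  }
  out <- data.frame(x = pos[, 1L], y = pos[, 2L])
  attr(out, "spacing") <- d
  attr(out, "cycle") <- cycle
  out
}

#' Assign wavefront onset times to nuclei
#'
#' Each nucleus is reached by the earlier of the two pole fronts:
#' `t = start_p + |x - x_p| / v_p`, minimised over poles, plus optional
#' Gaussian timing noise.
#'
#' @param positions Data frame with columns `x`, `y` (µm).
#' @param front A [front_spec()].
#' @param seed Integer seed for the timing noise.
#' @return Numeric vector of onset times (s), one per nucleus.
#' @export
assign_front_onsets <- function(positions, front, seed = 1) {
  stopifnot(inherits(front, "front_spec"), nrow(positions) > 0L)
  arrival <- sapply(1:2, function(p) {
    front$start_times[p] +
      abs(positions$x - front$pole_positions[p]) / front$speeds[p]
  })
  t0 <- if (is.matrix(arrival)) pmin(arrival[, 1L], arrival[, 2L])
        else min(arrival)
  if (front$timing_noise_sd > 0)
    t0 <- t0 + with_seed(seed, stats::rnorm(length(t0), 0,
                                            front$timing_noise_sd))
  t0
}

# Ellipse (a, b, theta) of one nucleus at one time, given its onsets.
# Returns also whether the mother has split by time t.
shape_at_time <- function(t, t_meta, t_ana, params) {
  r0 <- params$interphase_radius
  t_split <- t_ana + params$anaphase_duration
  if (t < t_meta) {
    list(a = r0, b = r0, theta = 0, split = FALSE)
  } else if (t < t_ana) {
    asp <- params$metaphase_aspect
    list(a = r0 * sqrt(asp), b = r0 / sqrt(asp),
         theta = params$metaphase_orientation, split = FALSE)
  } else if (t < t_split) {
    frac <- (t - t_ana) / params$anaphase_duration
    asp <- params$metaphase_aspect +
      frac * (params$anaphase_aspect - params$metaphase_aspect)
    list(a = r0 * sqrt(asp), b = r0 / sqrt(asp),
         theta = wrap_axial(params$metaphase_orientation +
                              params$orientation_flip), split = FALSE)
  } else {
    list(a = params$daughter_radius, b = params$daughter_radius,
         theta = 0, split = TRUE)
  }
}

#' Shape timeline of a dividing nucleus
#'
#' Builds the per-frame ellipse sequence of one nucleus: circle in
#' interphase, compressed ellipse between metaphase and anaphase onset, a
#' sudden orientation flip with progressive elongation after anaphase onset,
#' and a split into two daughter circles at the endpoints of the mother's
#' long axis.
#'
#' @param center Length-2 numeric, nucleus center (µm).
#' @param t_meta,t_ana Metaphase and anaphase onset times (s);
#'   `t_meta < t_ana` required.
#' @param params A [shape_params()].
#' @param times Numeric vector of frame times (s).
#' @return A list with `mother` (data frame `t, x, y, a, b, theta` up to the
#'   split) and `daughters` (data frame of the two daughter centers and the
#'   split time, or `NULL` if the movie ends before the split).
#' @export
synthesize_shape_timeline <- function(center, t_meta, t_ana, params, times) {
  stopifnot(inherits(params, "shape_params"), t_meta < t_ana)
  t_split <- t_ana + params$anaphase_duration
  pre <- times[times < t_split]
  shp <- lapply(pre, shape_at_time, t_meta = t_meta, t_ana = t_ana,
                params = params)
  mother <- data.frame(
    t = pre,
    x = center[1L], y = center[2L],
    a = vapply(shp, `[[`, numeric(1), "a"),
    b = vapply(shp, `[[`, numeric(1), "b"),
    theta = vapply(shp, `[[`, numeric(1), "theta"))
  daughters <- NULL
  if (any(times >= t_split)) {
    a_end <- params$interphase_radius * sqrt(params$anaphase_aspect)
    th_end <- wrap_axial(params$metaphase_orientation +
                           params$orientation_flip)
    off <- a_end * c(cos(th_end), sin(th_end))
    daughters <- data.frame(
      x = center[1L] + c(off[1L], -off[1L]),
      y = center[2L] + c(off[2L], -off[2L]),
      t_split = t_split)
  }
  list(mother = mother, daughters = daughters)
}

#' Collective displacement response
#'
#' After its onset, each nucleus relaxes along the long axis towards a new
#' equilibrium: `dx(t) = A * sign(x_mid - x) * (1 - exp(-(t - t0)/tau))` for
#' `t > t0`, zero before.  Motion is along x only; nuclei in each half move
#' towards the midplane, the pattern observed in slice-averaged displacement
#' kymographs.
#'
#' @param positions Data frame with column `x` (µm).
#' @param onsets Onset time per nucleus (s).
#' @param times Frame times (s).
#' @param amplitude Displacement plateau (µm).
#' @param relaxation_time Relaxation time constant (s), > 0.
#' @param x_mid Midpoint of the long axis (µm); defaults to `mean(range(x))`.
#' @return Matrix `[nucleus, time]` of x-displacements (µm).
#' @export
synthesize_displacements <- function(positions, onsets, times,
                                     amplitude = 2, relaxation_time = 60,
                                     x_mid = NULL) {
  stop_if_not_positive(relaxation_time = relaxation_time)
  if (is.null(x_mid)) x_mid <- mean(range(positions$x))
  sgn <- sign(x_mid - positions$x)
  out <- matrix(0, nrow = nrow(positions), ncol = length(times))
  for (j in seq_along(times)) {
    dt <- times[j] - onsets
    act <- dt > 0
    out[act, j] <- amplitude * sgn[act] * (1 - exp(-dt[act] / relaxation_time))
  }
  out
}

# Rasterize one anisotropic Gaussian blob into `img` (matrix, rows = y from
# top).  Semi-axes are interpreted as half-height radii, so the rendered
# blob's half-height contour is the stated ellipse; the PSF width adds in
# quadrature.
render_blob <- function(img, geometry, x, y, a, b, theta, peak, psf_um) {
  hh <- sqrt(2 * log(2))                 # half-height radius in sigma units
  sa <- sqrt((a / hh)^2 + psf_um^2)
  sb <- sqrt((b / hh)^2 + psf_um^2)
  px <- geometry$pixel_size
  nx <- ncol(img); ny <- nrow(img)
  ext <- 4 * max(sa, sb)
  c1 <- max(1L, floor((x - ext) / px)); c2 <- min(nx, ceiling((x + ext) / px))
  # row r covers y in [width - r*px, width - (r-1)*px]
  r1 <- max(1L, floor((geometry$width_y - (y + ext)) / px))
  r2 <- min(ny, ceiling((geometry$width_y - (y - ext)) / px))
  if (c1 > c2 || r1 > r2) return(img)
  xc <- (seq.int(c1, c2) - 0.5) * px
  yc <- geometry$width_y - (seq.int(r1, r2) - 0.5) * px
  dx <- outer(yc * 0, xc - x, `+`)
  dy <- outer(yc - y, xc * 0, `+`)
  ct <- cos(theta); st <- sin(theta)
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  img[r1:r2, c1:c2] <- img[r1:r2, c1:c2] +
    peak * exp(-0.5 * ((u / sa)^2 + (v / sb)^2))
  img
}

#' Render an ellipse table into an 8-bit movie
#'
#' Each nucleus becomes an anisotropic Gaussian blob whose half-height
#' contour is the stated ellipse; the point-spread function width is added in
#' quadrature.  Additive Gaussian noise and optional Poisson shot noise are
#' applied before quantization to 8-bit.
#'
#' @param states Data frame with columns `frame` (1-based), `x`, `y`, `a`,
#'   `b`, `theta` (physical units, µm / radians).
#' @param geometry An [embryo_geometry()].
#' @param psf_sigma PSF standard deviation in pixels (>= 0.5).
#' @param peak Peak blob intensity before noise (counts, <= 255).
#' @param gaussian_sd Additive noise standard deviation (counts).
#' @param poisson Logical; apply shot noise to the noiseless image.
#' @param seed Integer seed for the noise.
#' @param n_frames Number of frames; defaults to `max(states$frame)`.
#' @return A list of class `image_stack`: `frames` (list of matrices, row 1 =
#'   top of the embryo), `pixel_size`, `frame_interval`.
#' @export
render_movie <- function(states, geometry, psf_sigma = 1, peak = 200,
                         gaussian_sd = 0, poisson = FALSE, seed = 1,
                         n_frames = NULL) {
  stopifnot(inherits(geometry, "embryo_geometry"), psf_sigma >= 0.5)
  px <- geometry$pixel_size
  nx <- ceiling(geometry$length_x / px)
  ny <- ceiling(geometry$width_y / px)
  if (is.null(n_frames)) n_frames <- max(states$frame)
  inside <- states$x >= 0 & states$x <= geometry$length_x &
    states$y >= 0 & states$y <= geometry$width_y
  if (any(!inside)) {
    warning(sum(!inside), " nuclei outside the frame were clipped")
    states <- states[inside, , drop = FALSE]
  }
  psf_um <- psf_sigma * px
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(f) {
    img <- matrix(0, nrow = ny, ncol = nx)
    sub <- states[states$frame == f, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      img <- render_blob(img, geometry, sub$x[i], sub$y[i], sub$a[i],
                         sub$b[i], sub$theta[i], peak, psf_um)
    if (poisson) img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                               nrow = ny)
    if (gaussian_sd > 0) img <- img + stats::rnorm(length(img), 0, gaussian_sd)
    matrix(as.integer(pmin(pmax(round(img), 0), 255)), nrow = ny)
  }))
  structure(list(frames = frames, pixel_size = px,
                 frame_interval = geometry$frame_interval),
            class = "image_stack")
}

#' Generate a ground-truthed synthetic embryo movie for one cycle
#'
#' Builds the full synthetic observation for a single division cycle: nuclei
#' on a jittered lattice, two-pole metaphase-onset wavefront, constant
#' metaphase-to-anaphase interval, the mitotic shape sequence ending in a
#' division, and the collective displacement response.  Optionally renders
#' the movie.
#'
#' @param geometry An [embryo_geometry()].
#' @param schedule A [cycle_schedule()].
#' @param cycle Cycle to simulate.
#' @param front A [front_spec()] for the metaphase-onset wavefront.
#' @param shape A [shape_params()].
#' @param jitter_frac Lattice jitter fraction.
#' @param displacement_amplitude,displacement_tau Displacement response
#'   parameters (µm, s); amplitude 0 disables displacements.
#' @param t_end Movie end time (s); defaults to covering all splits plus
#'   30 s.
#' @param render Logical; render the 8-bit movie.
#' @param psf_sigma,peak,gaussian_sd,poisson Rendering parameters, see
#'   [render_movie()].
#' @param seed Integer master seed.
#' @return A list with `truth` (per-frame ellipse table: frame, id,
#'   parent_id, x_um, y_um, a_um, b_um, theta_rad, cycle), `onsets` (per
#'   nucleus id: x, t_meta, t_ana, t_split), `positions`, `times`, and
#'   `stack` (an `image_stack`, or `NULL`).
#' @export
synth_embryo_movie <- function(geometry, schedule, cycle, front,
                               shape = shape_params(),
                               jitter_frac = 0.1,
                               displacement_amplitude = 0,
                               displacement_tau = 60,
                               t_end = NULL, render = TRUE,
                               psf_sigma = 1, peak = 200, gaussian_sd = 0,
                               poisson = FALSE, seed = 1) {
  pos <- place_nuclei(geometry, schedule, cycle, jitter_frac,
                      seed = derive_seed(seed, "place"))
  ci <- match(cycle, schedule$cycles)
  t_meta <- assign_front_onsets(pos, front, seed = derive_seed(seed, "onset"))
  t_meta <- t_meta - min(t_meta) + 20 * geometry$frame_interval
  t_ana <- t_meta + schedule$mitosis_duration[ci]
  t_split <- t_ana + shape$anaphase_duration
  if (is.null(t_end)) t_end <- max(t_split) + 30 * geometry$frame_interval
  times <- seq(0, t_end, by = geometry$frame_interval)
  n <- nrow(pos)
  dx <- if (displacement_amplitude > 0)
    synthesize_displacements(pos, t_meta, times, displacement_amplitude,
                             displacement_tau)
  else matrix(0, n, length(times))

  rows <- vector("list", 3L * n)
  onset_tab <- data.frame(id = seq_len(n), x = pos$x, y = pos$y,
                          t_meta = t_meta, t_ana = t_ana, t_split = t_split)
  for (i in seq_len(n)) {
    tl <- synthesize_shape_timeline(c(pos$x[i], pos$y[i]), t_meta[i],
                                    t_ana[i], shape, times)
    m <- tl$mother
    fidx <- match(m$t, times)
    rows[[i]] <- data.frame(frame = fidx, id = i, parent_id = NA_integer_,
                            x_um = m$x + dx[i, fidx], y_um = m$y,
                            a_um = m$a, b_um = m$b, theta_rad = m$theta,
                            cycle = cycle)
    if (!is.null(tl$daughters)) {
      post <- which(times >= tl$daughters$t_split[1L])
      for (k in 1:2) {
        rows[[n * k + i]] <- data.frame(
          frame = post, id = n * k + i, parent_id = i,
          x_um = tl$daughters$x[k] + dx[i, post],
          y_um = tl$daughters$y[k],
          a_um = shape$daughter_radius, b_um = shape$daughter_radius,
          theta_rad = 0, cycle = cycle + 1L)
      }
    }
  }
  truth <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  truth <- truth[order(truth$frame, truth$id), ]
  rownames(truth) <- NULL
  stack <- NULL
  if (render) {
    st <- data.frame(frame = truth$frame, x = truth$x_um, y = truth$y_um,
                     a = truth$a_um, b = truth$b_um, theta = truth$theta_rad)
    stack <- render_movie(st, geometry, psf_sigma, peak, gaussian_sd,
                          poisson, seed = derive_seed(seed, "render"),
                          n_frames = length(times))
  }
  list(truth = truth, onsets = onset_tab, positions = pos, times = times,
       stack = stack)
}

#' Write an image stack as a multi-frame 8-bit TIFF
#'
#' @param stack An `image_stack` from [render_movie()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  imgs <- lapply(stack$frames, function(m) m / 255)
  tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a grayscale TIFF stack
#'
#' @param path TIFF file path.
#' @param pixel_size Pixel size (µm/px).
#' @param frame_interval Frame interval (s).
#' @return An `image_stack`.
#' @export
read_stack_tiff <- function(path, pixel_size = 1, frame_interval = 1) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(imgs, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m * 255
  })
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_stack")
}
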