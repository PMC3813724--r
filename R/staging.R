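#' Oriented axes-ratio series of a track
#'
#' The staging observable is the ratio of the ellipse's extent along the
#' embryo's long axis (x) to its extent along y, computed from the fitted
#' `(a, b, theta)`.  Using axis projections rather than the raw `a/b` makes
#' the anaphase orientation flip appear as a crossing of the ratio through 1
#' (below 1 while the metaphase plate lies across the long axis, above 1
#' after the flip).  A circle gives exactly 1 regardless of `theta`.
#'
#' @param track Data frame with columns `t_s`, `a_um`, `b_um`, `theta_rad`
#'   (one row per frame, time-ordered).
#' @param smooth_window Moving-median window (odd number of frames; 1
#'   disables smoothing).
#' @return Data frame with columns `t_s` and `rho`.
#' @export
axes_ratio_series <- function(track, smooth_window = 3) {
  stopifnot(nrow(track) >= smooth_window)
  ext_x <- sqrt((track$a_um * cos(track$theta_rad))^2 +
                  (track$b_um * sin(track$theta_rad))^2)
  ext_y <- sqrt((track$a_um * sin(track$theta_rad))^2 +
                  (track$b_um * cos(track$theta_rad))^2)
  rho <- ext_x / ext_y
  if (smooth_window > 1L && length(rho) >= smooth_window)
    rho <- as.numeric(stats::runmed(rho, smooth_window, endrule = "median"))
  data.frame(t_s = track$t_s, rho = rho)
}

#' Slice-average a per-track quantity along the long axis
#'
#' Partitions the x-range into slices of fixed width and computes, per slice
#' and per frame, the mean and sample standard deviation of a quantity over
#' the tracks currently inside the slice.  Empty slice/frame cells are
#' `NA` (flagged missing, not zero).
#'
#' @param values Data frame with columns `frame`, `t_s`, `x` (µm) and
#'   `value`.
#' @param slice_width Slice width (µm), > 0.
#' @param x_range Optional length-2 range to slice; defaults to the data
#'   range.
#' @return An object of class `slice_series`: list with `edges`, `x_centers`,
#'   `frames`, `times`, and matrices `mean`, `sd`, `n` of dimension
#'   `(n_slices, n_frames)`.
#' @export
slice_average <- function(values, slice_width, x_range = NULL) {
  stop_if_not_positive(slice_width = slice_width)
  if (is.null(x_range)) x_range <- range(values$x)
  n_slices <- max(1L, ceiling((x_range[2L] - x_range[1L]) / slice_width))
  edges <- x_range[1L] + slice_width * (0:n_slices)
  frames <- sort(unique(values$frame))
  times <- values$t_s[match(frames, values$frame)]
  si <- findInterval(values$x, edges, rightmost.closed = TRUE)
  fi <- match(values$frame, frames)
  ns <- length(edges) - 1L
  ok <- si >= 1L & si <= ns
  key <- (si[ok] - 1L) + ns * (fi[ok] - 1L)
  sums <- rowsum(values$value[ok], key)
  sqs <- rowsum(values$value[ok]^2, key)
  cnt <- rowsum(rep(1, sum(ok)), key)
  idx <- as.integer(rownames(sums)) + 1L
  mean_m <- sd_m <- matrix(NA_real_, ns, length(frames))
  n_m <- matrix(0L, ns, length(frames))
  mean_m[idx] <- sums / cnt
  n_m[idx] <- as.integer(cnt)
  var_ <- (sqs - sums^2 / cnt) / pmax(cnt - 1, 1)
  sd_m[idx] <- ifelse(cnt > 1, sqrt(pmax(var_, 0)), NA_real_)
  structure(list(edges = edges,
                 x_centers = (edges[-1L] + edges[-length(edges)]) / 2,
                 frames = frames, times = times,
                 mean = mean_m, sd = sd_m, n = n_m),
            class = "slice_series")
}

# First index at which `flag` stays TRUE for >= persistence consecutive
# entries, or NA.
first_persistent <- function(flag, persistence) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= persistence)
  if (length(hit) == 0L) return(NA_integer_)
  ends[hit[1L]] - r$lengths[hit[1L]] + 1L
}

#' Detect metaphase onset per slice
#'
#' The interphase-to-metaphase transition is sharp: the slice-mean axes
#' ratio leaves its interphase baseline of 1.  The onset is the first frame
#' at which `|rho - 1|` exceeds `deviation` for at least `persistence`
#' consecutive frames, outside a refractory exclusion window after any
#' previous detected event (preventing re-detection of the same transition
#' across cycles).
#'
#' @param slice_series A `slice_series` of the axes ratio.
#' @param deviation Deviation threshold from the neutral ratio 1.
#' @param persistence Minimum run length (frames).
#' @param refractory Exclusion window after an event (s).
#' @return Data frame of onset events: `x_um`, `t_s`, `marker`
#'   (`"metaphase"`), `cycle` (ordinal per slice), `slice_id`.  Slices with
#'   no crossing contribute no rows.
#' @export
detect_metaphase_onset <- function(slice_series, deviation = 0.15,
                                   persistence = 3, refractory = 0) {
  stopifnot(inherits(slice_series, "slice_series"))
  out <- list()
  for (s in seq_along(slice_series$x_centers)) {
    rho <- slice_series$mean[s, ]
    if (all(is.na(rho))) next
    flag <- abs(rho - 1) > deviation
    times <- slice_series$times
    start <- 1L
    cyc <- 0L
    while (start <= length(flag)) {
      rel <- first_persistent(flag[start:length(flag)], persistence)
      if (is.na(rel)) break
      i <- start + rel - 1L
      cyc <- cyc + 1L
      out[[length(out) + 1L]] <- data.frame(
        x_um = slice_series$x_centers[s], t_s = times[i],
        marker = "metaphase", cycle = cyc, slice_id = s)
      # skip past this event plus the refractory window and wait for the
      # series to return to baseline
      after <- which(times > times[i] + refractory & !flag &
                       seq_along(times) > i)
      if (length(after) == 0L) break
      start <- after[1L]
    }
  }
  if (length(out) == 0L)
    return(data.frame(x_um = numeric(0), t_s = numeric(0),
                      marker = character(0), cycle = integer(0),
                      slice_id = integer(0)))
  do.call(rbind, out)
}

#' Detect metaphase onset of a single track
#'
#' Per-track counterpart of [detect_metaphase_onset()]: the first frame at
#' which the track's own axes ratio deviates from 1 by more than
#' `deviation` for at least `persistence` consecutive frames.
#'
#' @param track Data frame with `t_s`, `x_um`, `a_um`, `b_um`, `theta_rad`.
#' @param deviation,persistence As in [detect_metaphase_onset()].
#' @param smooth_window Moving-median window for the ratio series.
#' @return One-row data frame (`x_um`, `t_s`, `marker = "metaphase"`), or a
#'   zero-row frame.
#' @export
detect_metaphase_onset_track <- function(track, deviation = 0.15,
                                         persistence = 3,
                                         smooth_window = 3) {
  empty <- data.frame(x_um = numeric(0), t_s = numeric(0),
                      marker = character(0))
  if (nrow(track) < max(persistence, smooth_window)) return(empty)
  rs <- axes_ratio_series(track, smooth_window)
  i <- first_persistent(abs(rs$rho - 1) > deviation, persistence)
  if (is.na(i)) return(empty)
  data.frame(x_um = track$x_um[i], t_s = track$t_s[i], marker = "metaphase")
}

#' Onset events from a track table
#'
#' Runs the per-track metaphase and anaphase detectors over every track of
#' a movie and assembles the onset-event table consumed by the wavefront
#' kinematics stage.
#'
#' @param tracks Track table from [track_movie()] (or the synthetic truth
#'   table with matching columns).
#' @param deviation,persistence,smooth_window Metaphase detector settings.
#' @param angle_jump,ana_persistence Anaphase detector settings.
#' @param cycle Cycle label attached to the events.
#' @return Data frame `x_um`, `t_s`, `marker`, `cycle`, `id`.
#' @export
stage_tracks <- function(tracks, deviation = 0.15, persistence = 3,
                         smooth_window = 3, angle_jump = pi / 4,
                         ana_persistence = 2, cycle = NA_integer_) {
  out <- list()
  for (id in unique(tracks$id)) {
    tr <- tracks[tracks$id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), ]
    met <- detect_metaphase_onset_track(tr, deviation, persistence,
                                        smooth_window)
    if (nrow(met) > 0L) {
      ana <- detect_anaphase_onset(tr, angle_jump, ana_persistence,
                                   t_meta = met$t_s[1L])
      ev <- rbind(met, ana)
      ev$id <- id
      out[[length(out) + 1L]] <- ev
    }
  }
  if (length(out) == 0L)
    return(data.frame(x_um = numeric(0), t_s = numeric(0),
                      marker = character(0), cycle = integer(0),
                      id = integer(0)))
  ev <- do.call(rbind, out)
  ev$cycle <- cycle
  ev[, c("x_um", "t_s", "marker", "cycle", "id")]
}

#' Detect anaphase onset of a track
#'
#' Anaphase onset is marked by a sudden flip of the ellipse orientation
#' (close to 90 degrees) accompanied by subsequent elongation.  The detector
#' finds the first frame after the metaphase onset at which the
#' frame-to-frame orientation difference (wrapped to `[0, pi/2]`) exceeds
#' `angle_jump` and the raw aspect ratio `a/b` does not decrease over the
#' following `persistence` frames.
#'
#' @param track Data frame with `t_s`, `a_um`, `b_um`, `theta_rad`.
#' @param angle_jump Minimum orientation jump (radians).
#' @param persistence Number of following frames over which the aspect must
#'   be non-decreasing.
#' @param t_meta Optional metaphase-onset time (s); jumps before it are
#'   ignored.
#' @return One-row data frame (`x_um`, `t_s`, `marker = "anaphase"`), or a
#'   zero-row frame if no event is found before the track ends.
#' @export
detect_anaphase_onset <- function(track, angle_jump = pi / 4,
                                  persistence = 2, t_meta = -Inf) {
  empty <- data.frame(x_um = numeric(0), t_s = numeric(0),
                      marker = character(0))
  n <- nrow(track)
  if (n < 3L) return(empty)
  dtheta <- axial_diff(track$theta_rad[-1L], track$theta_rad[-n])
  aspect <- track$a_um / track$b_um
  for (i in which(dtheta > angle_jump)) {
    t_i <- track$t_s[i + 1L]
    if (t_i <= t_meta) next
    last <- min(n, i + 1L + persistence)
    if (last - (i + 1L) < 1L) next
    seg <- aspect[(i + 1L):last]
    if (all(diff(seg) >= -1e-9)) {
      return(data.frame(x_um = track$x_um[i + 1L], t_s = t_i,
                        marker = "anaphase"))
    }
  }
  empty
}

#' Slice-averaged displacement response
#'
#' Computes per-lineage displacements along the long axis,
#' `dx(t) = x(t) - x(t_ref)`, replacing a divided nucleus by the mean
#' position of its two daughters after the split, then slice-averages them.
#' Lineages whose mother disappears without two linked daughters are
#' excluded.
#'
#' @param tracks Track table from [track_movie()] (or the synthetic truth
#'   table with the same columns).
#' @param slice_width Slice width (µm).
#' @param component `"x"` (default) or `"y"`.
#' @return A list: `series` (a `slice_series` of the displacement),
#'   `per_track` (data frame `frame`, `t_s`, `root_id`, `x`, `value`),
#'   `excluded` (root ids dropped for broken lineage).
#' @export
displacement_series <- function(tracks, slice_width = 25, component = "x") {
  col <- if (component == "x") "x_um" else "y_um"
  roots <- unique(tracks$id[is.na(tracks$parent_id)])
  children <- split(tracks$id[!is.na(tracks$parent_id)],
                    tracks$parent_id[!is.na(tracks$parent_id)])
  per <- list()
  excluded <- integer(0)
  for (r in roots) {
    mrows <- tracks[tracks$id == r, , drop = FALSE]
    mrows <- mrows[order(mrows$frame), ]
    kids <- children[[as.character(r)]]
    kids <- unique(kids)
    series <- data.frame(frame = mrows$frame, t_s = mrows$t_s,
                         x = mrows$x_um, value = mrows[[col]])
    if (length(kids) == 2L) {
      krows <- tracks[tracks$id %in% kids, , drop = FALSE]
      agg_v <- tapply(krows[[col]], krows$frame, mean)
      agg_x <- tapply(krows$x_um, krows$frame, mean)
      agg_t <- tapply(krows$t_s, krows$frame, mean)
      fr <- as.integer(names(agg_v))
      series <- rbind(series,
                      data.frame(frame = fr, t_s = as.numeric(agg_t),
                                 x = as.numeric(agg_x),
                                 value = as.numeric(agg_v)))
    } else if (length(kids) > 0L) {
      excluded <- c(excluded, r)
      next
    } else if (max(mrows$frame) < max(tracks$frame)) {
      # mother vanished with no linked daughters: broken lineage
      excluded <- c(excluded, r)
      next
    }
    series <- series[order(series$frame), ]
    series$value <- series$value - series$value[1L]
    series$root_id <- r
    # slice membership follows the lineage's reference x position
    series$x <- series$x[1L]
    per[[length(per) + 1L]] <- series
  }
  if (length(per) == 0L)
    stop("no intact lineages to compute displacements from")
  per <- do.call(rbind, per)
  list(series = slice_average(per[, c("frame", "t_s", "x", "value")],
                              slice_width),
       per_track = per, excluded = excluded)
}

#' Kymograph matrix of a slice series
#'
#' @param slice_series A `slice_series`.
#' @param neutral Neutral value of the diverging scale (1 for the axes
#'   ratio, 0 for displacements); stored as an attribute.
#' @return Numeric matrix `(n_slices, n_frames)`; missing cells are `NA`.
#' @export
kymograph <- function(slice_series, neutral = 1) {
  stopifnot(inherits(slice_series, "slice_series"))
  m <- slice_series$mean
  dimnames(m) <- list(slice = signif(slice_series$x_centers, 6),
                      frame = slice_series$frames)
  attr(m, "neutral") <- neutral
  m
}
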