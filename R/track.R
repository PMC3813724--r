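#' Link one frame of detections to active tracks
#'
#' Greedy mutual-nearest-neighbour assignment: a detection extends a track
#' only if each is the other's nearest candidate and their distance is below
#' `max_disp_frac` times the track's current radius.  At 1 frame/s nuclei
#' move much less than their own radius between frames, so this simple rule
#' is sufficient; anything farther starts a new track.
#'
#' @param active Data frame of the last detection of each active track
#'   (columns `id`, `x`, `y`, `a`, `b`, `theta`); may have zero rows.
#' @param detections Data frame from [detect_ellipses()] for one frame.
#' @param max_disp_frac Maximum displacement as a fraction of the nuclear
#'   radius (geometric mean of the semi-axes).
#' @return A list: `matches` (data frame `track_id`, `det_row`), `lost`
#'   (track ids with no match), `new` (unmatched detection rows).
#' @export
link_frames <- function(active, detections, max_disp_frac = 1) {
  if (nrow(active) == 0L || nrow(detections) == 0L) {
    return(list(matches = data.frame(track_id = integer(0),
                                     det_row = integer(0)),
                lost = active$id, new = seq_len(nrow(detections))))
  }
  dmat <- sqrt(outer(active$x, detections$x, `-`)^2 +
                 outer(active$y, detections$y, `-`)^2)
  near_det <- apply(dmat, 1L, which.min)   # per track
  near_trk <- apply(dmat, 2L, which.min)   # per detection
  radius <- sqrt(active$a * active$b)
  mutual <- which(near_trk[near_det] == seq_len(nrow(active)) &
                    dmat[cbind(seq_len(nrow(active)), near_det)] <=
                    max_disp_frac * radius)
  matches <- data.frame(track_id = active$id[mutual],
                        det_row = near_det[mutual])
  list(matches = matches,
       lost = active$id[setdiff(seq_len(nrow(active)), mutual)],
       new = setdiff(seq_len(nrow(detections)), matches$det_row))
}

#' Resolve a division for a track that just ended
#'
#' A mother is accepted as having divided when its final shape was highly
#' elongated and exactly two nearly circular new detections appear within a
#' capture radius of its long-axis endpoints in the next frame.
#'
#' @param mother One-row data frame: last detection of the ended track
#'   (`x`, `y`, `a`, `b`, `theta`).
#' @param candidates Data frame of unmatched detections in the current frame.
#' @param min_mother_aspect Minimum final aspect ratio of the mother.
#' @param max_daughter_aspect Maximum aspect ratio of a daughter.
#' @param capture_frac Capture radius around each long-axis endpoint, as a
#'   fraction of the mother semi-major.
#' @return Integer vector of the two daughter candidate rows, or `NULL` if
#'   no division is declared (below the elongation threshold, or an
#'   ambiguous candidate set).
#' @export
resolve_division <- function(mother, candidates,
                             min_mother_aspect = 2.5,
                             max_daughter_aspect = 1.3,
                             capture_frac = 0.6) {
  if (nrow(candidates) == 0L) return(NULL)
  if (mother$a / mother$b < min_mother_aspect) return(NULL)
  circ <- candidates$a / candidates$b <= max_daughter_aspect
  picks <- integer(0)
  for (s in c(1, -1)) {
    ex <- mother$x + s * mother$a * cos(mother$theta)
    ey <- mother$y + s * mother$a * sin(mother$theta)
    d <- sqrt((candidates$x - ex)^2 + (candidates$y - ey)^2)
    d[!circ] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j]) || d[j] > capture_frac * mother$a) return(NULL)
    picks <- c(picks, j)
  }
  if (picks[1L] == picks[2L]) return(NULL)   # one blob claimed twice
  picks
}

# Global endpoint-candidate assignment across all mothers lost in one frame:
# candidate/endpoint pairs are matched greedily by increasing distance with
# uniqueness on both sides, so adjacent simultaneous divisions cannot steal
# each other's daughters.  Returns a list of integer pairs indexed by mother
# row.
resolve_divisions_global <- function(mothers, candidates,
                                     min_mother_aspect = 2.5,
                                     max_daughter_aspect = 1.3,
                                     capture_frac = 0.6) {
  out <- vector("list", nrow(mothers))
  if (nrow(candidates) == 0L || nrow(mothers) == 0L) return(out)
  circ <- which(candidates$a / candidates$b <= max_daughter_aspect)
  if (length(circ) == 0L) return(out)
  pairs <- list()
  for (m in seq_len(nrow(mothers))) {
    mo <- mothers[m, ]
    if (mo$a / mo$b < min_mother_aspect) next
    for (s in 1:2) {
      sg <- c(1, -1)[s]
      ex <- mo$x + sg * mo$a * cos(mo$theta)
      ey <- mo$y + sg * mo$a * sin(mo$theta)
      d <- sqrt((candidates$x[circ] - ex)^2 + (candidates$y[circ] - ey)^2)
      ok <- which(d <= capture_frac * mo$a)
      for (k in ok)
        pairs[[length(pairs) + 1L]] <- c(m, s, circ[k], d[k])
    }
  }
  if (length(pairs) == 0L) return(out)
  pm <- do.call(rbind, pairs)
  pm <- pm[order(pm[, 4L]), , drop = FALSE]
  ep_taken <- matrix(NA_integer_, nrow(mothers), 2L)
  cand_taken <- rep(FALSE, nrow(candidates))
  for (r in seq_len(nrow(pm))) {
    m <- pm[r, 1L]; s <- pm[r, 2L]; k <- pm[r, 3L]
    if (!is.na(ep_taken[m, s]) || cand_taken[k]) next
    ep_taken[m, s] <- k
    cand_taken[k] <- TRUE
  }
  for (m in seq_len(nrow(mothers)))
    if (!anyNA(ep_taken[m, ])) out[[m]] <- as.integer(ep_taken[m, ])
  out
}

#' Detect and track nuclei across a movie
#'
#' Runs per-frame ellipse detection, mutual-nearest-neighbour linking and
#' division resolution over an image stack, producing division-aware tracks.
#'
#' @param stack An `image_stack` (see [render_movie()]), or a list of
#'   matrices plus `pixel_size`/`frame_interval`.
#' @param pixel_size,frame_interval Overrides when `stack` is a plain list.
#' @param use_bandpass Logical; bandpass-filter each frame first (recommended
#'   for noisy movies).
#' @param low_sigma,high_sigma Bandpass widths (px).
#' @param n_levels,min_area,merge_dist,win_radius Passed to
#'   [detect_ellipses()].
#' @param max_disp_frac Passed to [link_frames()].
#' @param min_mother_aspect,max_daughter_aspect,capture_frac Passed to
#'   [resolve_division()].
#' @return A data frame of tracked detections: `frame`, `id`, `parent_id`,
#'   `t_s`, `x_um`, `y_um`, `a_um`, `b_um`, `theta_rad`, `divided` (flag on
#'   the mother's rows).
#' @export
track_movie <- function(stack, pixel_size = NULL, frame_interval = NULL,
                        use_bandpass = FALSE, low_sigma = 1, high_sigma = 8,
                        n_levels = 16, min_area = 4, merge_dist = 2,
                        win_radius = 12, max_disp_frac = 1,
                        min_mother_aspect = 2.5, max_daughter_aspect = 1.3,
                        capture_frac = 0.6) {
  if (inherits(stack, "image_stack")) {
    frames <- stack$frames
    pixel_size <- stack$pixel_size
    frame_interval <- stack$frame_interval
  } else {
    frames <- stack
    if (is.null(pixel_size) || is.null(frame_interval))
      stop("pixel_size and frame_interval required for a plain frame list")
  }
  next_id <- 1L
  active <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                       a = numeric(0), b = numeric(0), theta = numeric(0))
  parent_of <- integer(0)      # named by id
  divided <- integer(0)        # ids of mothers that divided
  rows <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    img <- frames[[f]]
    if (use_bandpass) img <- bandpass(img, low_sigma, high_sigma)
    det <- detect_ellipses(img, pixel_size = pixel_size, n_levels = n_levels,
                           min_area = min_area, merge_dist = merge_dist,
                           win_radius = win_radius)
    lk <- link_frames(active, det, max_disp_frac)
    new_active <- list()
    # extend matched tracks
    if (nrow(lk$matches) > 0L) {
      ext <- det[lk$matches$det_row, , drop = FALSE]
      ext$id <- lk$matches$track_id
      new_active[[length(new_active) + 1L]] <-
        ext[, c("id", "x", "y", "a", "b", "theta")]
    }
    unmatched <- lk$new
    # division check: a mother's daughters appear in the frame where the
    # mother's own detection first goes missing
    lost_now <- active[active$id %in% lk$lost, , drop = FALSE]
    if (nrow(lost_now) > 0L && length(unmatched) > 0L) {
      cand <- det[unmatched, , drop = FALSE]
      links <- resolve_divisions_global(lost_now, cand, min_mother_aspect,
                                        max_daughter_aspect, capture_frac)
      used <- integer(0)
      for (m in seq_along(links)) {
        if (is.null(links[[m]])) next
        mom <- lost_now$id[m]
        divided <- c(divided, mom)
        for (k in links[[m]]) {
          child <- cand[k, , drop = FALSE]
          child$id <- next_id
          parent_of[as.character(next_id)] <- mom
          next_id <- next_id + 1L
          new_active[[length(new_active) + 1L]] <-
            child[, c("id", "x", "y", "a", "b", "theta")]
        }
        used <- c(used, links[[m]])
      }
      unmatched <- setdiff(unmatched, unmatched[used])
    }
    # remaining unmatched detections open parentless tracks
    if (length(unmatched) > 0L) {
      fresh <- det[unmatched, , drop = FALSE]
      fresh$id <- seq.int(next_id, length.out = nrow(fresh))
      next_id <- next_id + nrow(fresh)
      new_active[[length(new_active) + 1L]] <-
        fresh[, c("id", "x", "y", "a", "b", "theta")]
    }
    active <- if (length(new_active) > 0L) do.call(rbind, new_active)
              else active[0L, ]
    if (nrow(active) > 0L)
      rows[[f]] <- data.frame(frame = f, id = active$id,
                              t_s = (f - 1L) * frame_interval,
                              x_um = active$x, y_um = active$y,
                              a_um = active$a, b_um = active$b,
                              theta_rad = active$theta)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(frame = integer(0), id = integer(0),
                      parent_id = integer(0), t_s = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      a_um = numeric(0), b_um = numeric(0),
                      theta_rad = numeric(0), divided = logical(0)))
  out <- do.call(rbind, rows)
  out$parent_id <- unname(parent_of[as.character(out$id)])
  out$divided <- out$id %in% divided
  out[, c("frame", "id", "parent_id", "t_s", "x_um", "y_um", "a_um",
          "b_um", "theta_rad", "divided")]
}
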