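#' Embryo geometry
#'
#' Physical description of the imaged 2D projection of the embryo surface:
#' an elongated rectangle whose long axis is x (origin at the left pole) and
#' whose short axis is y.  Positions are stored in micrometres; images carry
#' a pixel size so conversion happens only at render/detection time.
#'
#' @param length_x Long-axis extent (µm).
#' @param width_y Short-axis extent (µm); must be smaller than `length_x`.
#' @param pixel_size Pixel edge (µm/px).
#' @param frame_interval Time between frames (s).
#' @return An object of class `embryo_geometry`.
#' @export
embryo_geometry <- function(length_x = 500, width_y = 180,
                            pixel_size = 1, frame_interval = 1) {
  stop_if_not_positive(length_x = length_x, width_y = width_y,
                       pixel_size = pixel_size, frame_interval = frame_interval)
  if (length_x <= width_y)
    stop("'length_x' must exceed 'width_y' (long axis convention)")
  structure(list(length_x = length_x, width_y = width_y,
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "embryo_geometry")
}

#' Division-cycle schedule
#'
#' Per-cycle nuclear spacing, cycle duration and mitosis duration.  Surface
#' nuclei double in number each cycle, so the nearest-neighbour spacing decays
#' exponentially: `d_n = d_n0 * 2^(-(n - n0)/nu_spacing)`.  The naive value
#' `nu_spacing = 2` corresponds to exact density doubling of a planar layer;
#' projection of the curved surface makes the measured exponent slightly
#' smaller, so it is exposed as a parameter.
#'
#' @param cycles Integer vector of consecutive cycle numbers (e.g. `10:13`).
#' @param base_spacing Nearest-neighbour spacing in the first cycle (µm).
#' @param nu_spacing Spacing decay exponent (dimensionless, default 2).
#' @param durations Cycle durations (s), one per cycle; recycled if scalar.
#' @param mitosis_duration Metaphase-onset to anaphase-onset interval (s),
#'   constant across cycles (recycled if scalar).
#' @return An object of class `cycle_schedule`.
#' @export
cycle_schedule <- function(cycles = 10:13, base_spacing = 12,
                           nu_spacing = 2, durations = 600,
                           mitosis_duration = 180) {
  cycles <- as.integer(cycles)
  stopifnot(length(cycles) >= 1L, !anyNA(cycles))
  stop_if_not_positive(base_spacing = base_spacing, nu_spacing = nu_spacing,
                       durations = durations,
                       mitosis_duration = mitosis_duration)
  durations <- rep_len(durations, length(cycles))
  mitosis_duration <- rep_len(mitosis_duration, length(cycles))
  structure(list(first_cycle = cycles[1L], cycles = cycles,
                 base_spacing = base_spacing, nu_spacing = nu_spacing,
                 durations = durations, mitosis_duration = mitosis_duration),
            class = "cycle_schedule")
}

#' Nuclear spacing for a cycle
#'
#' @param schedule A [cycle_schedule()].
#' @param cycle Cycle number(s).
#' @return Spacing `d_n` (µm).
#' @export
cycle_spacing <- function(schedule, cycle) {
  stopifnot(inherits(schedule, "cycle_schedule"))
  schedule$base_spacing *
    2^(-(cycle - schedule$first_cycle) / schedule$nu_spacing)
}

#' Two-pole wavefront specification
#'
#' Kinematic description of the onset wavefronts: one front starts near each
#' pole and propagates inwards at constant speed; a nucleus takes the earlier
#' of the two pole arrival times.
#'
#' @param pole_positions Two x-coordinates (µm) from which the fronts start.
#' @param start_times Front start times (s), one per pole.
#' @param speeds Front speeds (µm/s), one per pole; must be positive.
#' @param timing_noise_sd Gaussian noise on onset times (s), >= 0.
#' @return An object of class `front_spec`.
#' @export
front_spec <- function(pole_positions = c(0, 500), start_times = c(0, 0),
                       speeds = c(1, 1), timing_noise_sd = 0) {
  stopifnot(length(pole_positions) == 2L)
  start_times <- rep_len(start_times, 2L)
  speeds <- rep_len(speeds, 2L)
  if (any(!is.finite(speeds)) || any(speeds <= 0))
    stop("front speeds must be positive")
  if (timing_noise_sd < 0) stop("'timing_noise_sd' must be >= 0")
  structure(list(pole_positions = as.numeric(pole_positions),
                 start_times = as.numeric(start_times),
                 speeds = as.numeric(speeds),
                 timing_noise_sd = timing_noise_sd),
            class = "front_spec")
}

#' Mitotic shape-timeline parameters
#'
#' Parameters of the stereotyped shape sequence of the chromosomal signal:
#' circle in interphase, compressed ellipse at the metaphase plate, a sudden
#' ~90 degree flip of the orientation axis with further elongation at anaphase
#' onset, then a split into two nearly circular daughters at the endpoints of
#' the mother's long axis.
#'
#' @param interphase_radius Circle radius in interphase (µm).
#' @param metaphase_aspect Axis ratio of the metaphase ellipse (> 1).
#' @param anaphase_aspect Axis ratio reached before the split
#'   (> `metaphase_aspect`).
#' @param metaphase_orientation Major-axis angle of the metaphase ellipse
#'   (radians); default `pi/2`, i.e. the metaphase plate lies across the
#'   embryo's long axis.
#' @param orientation_flip Angle jump at anaphase onset (radians in (0, pi]),
#'   default `pi/2`.
#' @param daughter_radius Radius of the daughter circles (µm).
#' @param anaphase_duration Time from anaphase onset to the split (s).
#' @return An object of class `shape_params`.
#' @export
shape_params <- function(interphase_radius = 2.2, metaphase_aspect = 1.8,
                         anaphase_aspect = 3.2,
                         metaphase_orientation = pi / 2,
                         orientation_flip = pi / 2,
                         daughter_radius = 1.3, anaphase_duration = 30) {
  stop_if_not_positive(interphase_radius = interphase_radius,
                       daughter_radius = daughter_radius,
                       anaphase_duration = anaphase_duration)
  if (metaphase_aspect < 1 || anaphase_aspect < metaphase_aspect)
    stop("need anaphase_aspect >= metaphase_aspect >= 1")
  if (orientation_flip <= 0 || orientation_flip > pi)
    stop("'orientation_flip' must be in (0, pi]")
  structure(list(interphase_radius = interphase_radius,
                 metaphase_aspect = metaphase_aspect,
                 anaphase_aspect = anaphase_aspect,
                 metaphase_orientation = wrap_axial(metaphase_orientation),
                 orientation_flip = orientation_flip,
                 daughter_radius = daughter_radius,
                 anaphase_duration = anaphase_duration),
            class = "shape_params")
}
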