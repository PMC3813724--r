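# Shared small fixtures for the synthetic-embryo tests.

test_geometry <- function(length_x = 150, width_y = 45)
  embryo_geometry(length_x = length_x, width_y = width_y,
                  pixel_size = 1, frame_interval = 1)

test_schedule <- function(base_spacing = 16)
  cycle_schedule(cycles = 10:13, base_spacing = base_spacing,
                 nu_spacing = 2, durations = 600, mitosis_duration = 25)

test_shape <- function() shape_params(anaphase_duration = 10)

test_front <- function(length_x = 150, v = 3, noise = 0)
  front_spec(pole_positions = c(0, length_x), start_times = c(0, 0),
             speeds = c(v, v), timing_noise_sd = noise)

# One-cycle rendered movie used by several tracking/staging tests; cached
# per session because rendering plus tracking is the expensive step.
.movie_cache <- new.env(parent = emptyenv())
test_movie <- function(seed = 5) {
  key <- paste0("m", seed)
  if (is.null(.movie_cache[[key]])) {
    .movie_cache[[key]] <- synth_embryo_movie(
      test_geometry(), test_schedule(), 10, test_front(),
      test_shape(), jitter_frac = 0.08, seed = seed, psf_sigma = 0.5,
      displacement_amplitude = 1, displacement_tau = 20)
  }
  .movie_cache[[key]]
}
test_tracks <- function(seed = 5) {
  key <- paste0("t", seed)
  if (is.null(.movie_cache[[key]]))
    .movie_cache[[key]] <- track_movie(test_movie(seed)$stack)
  .movie_cache[[key]]
}
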