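#' Trajectory simulation configuration
#'
#' Bundles the acquisition parameters shared by all trajectory generators:
#' camera frame interval, static localization error, track-length law and
#' field of view.
#'
#' @param frame_interval Time between frames in seconds (default 0.01 s,
#'   i.e. 100 Hz acquisition).
#' @param localization_sigma Static localization error in micrometres,
#'   added independently to every coordinate of every detection
#'   (default 0.05 um).
#' @param min_track_length Minimum number of detections per emitted track
#'   (default 11: only tracks with more than 10 detections survive the
#'   reliability filter).
#' @param mean_track_length Mean lifetime, in frames, of the memoryless
#'   photobleaching law from which raw track lengths are drawn
#'   (default 20).  Lengths are geometric with this mean, conditioned on
#'   reaching `min_track_length`, so the realised mean of emitted tracks
#'   exceeds `mean_track_length` (see Details).
#' @param n_tracks Number of tracks to generate (default 500).
#' @param field_size Side of the square field of view in micrometres
#'   (default 6.5 um); starting positions are uniform in the field.
#' @param rng_seed Optional integer seed; when set, generators using this
#'   config are fully reproducible.
#'
#' @details Photobleaching is modelled as a constant per-frame death
#'   probability, giving geometrically distributed raw lifetimes with mean
#'   `mean_track_length`.  The detection filter discards raw tracks shorter
#'   than `min_track_length`; by memorylessness the emitted lengths are
#'   `min_track_length - 1 + Geometric(mean = mean_track_length)`.  With the
#'   defaults (mean 20, minimum 11) the realised mean length is 30 frames,
#'   consistent with a mean number of detections per trajectory of at least
#'   20 after the more-than-10-detections filter.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(frame_interval = 0.01,
                       localization_sigma = 0.05,
                       min_track_length = 11,
                       mean_track_length = 20,
                       n_tracks = 500,
                       field_size = 6.5,
                       rng_seed = NULL) {
  check_positive(frame_interval, "frame_interval")
  if (localization_sigma < 0) stop_domain("`localization_sigma` must be >= 0")
  if (min_track_length < 2) stop_domain("`min_track_length` must be >= 2")
  if (mean_track_length < min_track_length) {
    stop_domain("`mean_track_length` must be >= `min_track_length`")
  }
  check_positive(n_tracks, "n_tracks")
  check_positive(field_size, "field_size")
  structure(
    list(
      frame_interval = frame_interval,
      localization_sigma = localization_sigma,
      min_track_length = as.integer(min_track_length),
      mean_track_length = mean_track_length,
      n_tracks = as.integer(n_tracks),
      field_size = field_size,
      rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Trajectory simulation config\n")
  cat(sprintf("  frame interval     : %g s (%g Hz)\n",
              x$frame_interval, 1 / x$frame_interval))
  cat(sprintf("  localization sigma : %g um\n", x$localization_sigma))
  cat(sprintf("  track length       : geometric mean %g, min %d detections\n",
              x$mean_track_length, x$min_track_length))
  cat(sprintf("  tracks / field     : %d in %g um\n", x$n_tracks, x$field_size))
  if (!is.null(x$rng_seed)) cat(sprintf("  seed               : %d\n", x$rng_seed))
  invisible(x)
}

# draw emitted track lengths: geometric lifetime (mean = mean_track_length)
# conditioned on >= min_track_length, via memorylessness
draw_track_lengths <- function(n, config) {
  p <- 1 / config$mean_track_length
  config$min_track_length - 1L + stats::rgeom(n, p) + 1L
}
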