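#' Simulation configuration for a synthetic fish shoal
#'
#' Bundles every parameter of the synthetic shoal generator in one validated
#' object. The recording geometry mirrors a standard small-tank monitoring
#' set-up: a fixed overhead camera producing 640 x 480 pixel frames at 24
#' frames per second, 3.5-minute (210 s) analysis clips, and a disturbance
#' ("event", a hit on the tank) near the middle of the recording.
#'
#' The movement model is a cohesive correlated random walk with intermittent
#' (burst-and-coast) locomotion:
#' \itemize{
#'   \item each fish keeps a unit heading updated from its previous heading
#'     (`heading_persistence`), the mean heading of the group
#'     (`alignment_weight`), attraction towards the group centroid
#'     (`cohesion_weight`, per pixel of offset) and Gaussian jitter
#'     (`noise_sd`);
#'   \item the whole group alternates between "moving" bouts at `base_speed`
#'     and "hovering" at `hover_speed_frac * base_speed`. The long-run
#'     fraction of time spent moving is
#'     `activity_max * (1 - exp(-n_fish / activity_scale))`, so larger
#'     shoals are bolder and explore more of the arena, while bout lengths
#'     average `bout_length` seconds;
#'   \item each individual carries a lognormal boldness multiplier
#'     (`boldness_sd` on the log scale) on its swim speed, the dominant
#'     source of between-day variability for very small groups;
#'   \item a single fish, which in shoaling species barely moves when alone,
#'     additionally has its displacement scaled by `freeze_factor`;
#'   \item tank walls reflect.
#' }
#'
#' During the event window (`event_time`, `event_duration`) speeds are
#' multiplied by `event_speed_multiplier`, centroid attraction by
#' `event_cohesion_multiplier`, and (when either multiplier exceeds 1) the
#' group is startled into its moving state: a schooling burst.
#'
#' Identical configuration + seed gives bit-identical output everywhere.
#'
#' @param n_fish number of fish, >= 1.
#' @param arena_width,arena_height arena size in pixels.
#' @param fps frames per second.
#' @param clip_duration analysis-clip length in seconds (default 210 = 3.5 min).
#' @param recording_duration total recording length in seconds. The default
#'   840 s is the shortest recording holding three disjoint basal clips, the
#'   event and one response clip; a full one-hour protocol is `3600`.
#' @param base_speed swim speed during moving bouts, pixels/frame.
#' @param cohesion_weight attraction to the group centroid, per pixel offset.
#' @param heading_persistence weight of the previous heading, in `[0, 1)`.
#' @param alignment_weight weight of the group mean heading.
#' @param noise_sd per-axis sd of the heading jitter.
#' @param freeze_factor displacement scaling applied when `n_fish == 1`,
#'   in `(0, 1]`.
#' @param boldness_sd sd of per-fish lognormal speed multipliers (log scale).
#' @param activity_max,activity_scale moving-time fraction saturation level
#'   and group-size scale (see Details).
#' @param bout_length mean length of a moving bout, seconds.
#' @param hover_speed_frac speed during hovering, as a fraction of
#'   `base_speed`.
#' @param event_time event onset in seconds from recording start, or `NA`
#'   for no event.
#' @param event_duration length of the schooling burst in seconds.
#' @param event_speed_multiplier speed multiplier during the event, > 0
#'   (values > 1 give a burst; 1 leaves the trace unchanged).
#' @param event_cohesion_multiplier centroid-attraction multiplier during the
#'   event.
#' @param fish_radius radius in pixels used when rendering frames.
#' @param seed integer RNG seed recorded in all outputs.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_fish = 13, seed = 1)
#' cfg$fps * cfg$clip_duration  # 5040 frames per clip
#' @export
sim_config <- function(n_fish,
                       arena_width = 640,
                       arena_height = 480,
                       fps = 24,
                       clip_duration = 210,
                       recording_duration = 840,
                       base_speed = 4,
                       cohesion_weight = 0.05,
                       heading_persistence = 0.8,
                       alignment_weight = 0.5,
                       noise_sd = 0.6,
                       freeze_factor = 0.1,
                       boldness_sd = 0.5,
                       activity_max = 0.6,
                       activity_scale = 8,
                       bout_length = 5,
                       hover_speed_frac = 0.03,
                       event_time = NA_real_,
                       event_duration = 10,
                       event_speed_multiplier = 3,
                       event_cohesion_multiplier = 2,
                       fish_radius = 3,
                       seed = 1L) {
  cfg <- list(
    n_fish = as.integer(n_fish),
    arena_width = arena_width, arena_height = arena_height,
    fps = fps, clip_duration = clip_duration,
    recording_duration = recording_duration,
    base_speed = base_speed, cohesion_weight = cohesion_weight,
    heading_persistence = heading_persistence,
    alignment_weight = alignment_weight, noise_sd = noise_sd,
    freeze_factor = freeze_factor, boldness_sd = boldness_sd,
    activity_max = activity_max, activity_scale = activity_scale,
    bout_length = bout_length, hover_speed_frac = hover_speed_frac,
    event_time = event_time, event_duration = event_duration,
    event_speed_multiplier = event_speed_multiplier,
    event_cohesion_multiplier = event_cohesion_multiplier,
    fish_radius = fish_radius, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.na(cfg$n_fish) || cfg$n_fish < 1L) {
    stop("`n_fish` must be a count >= 1", call. = FALSE)
  }
  if (cfg$arena_width <= 0 || cfg$arena_height <= 0) {
    stop("arena dimensions must be positive", call. = FALSE)
  }
  if (cfg$base_speed <= 0) stop("`base_speed` must be positive", call. = FALSE)
  if (cfg$fps <= 0) stop("`fps` must be positive", call. = FALSE)
  if (cfg$freeze_factor <= 0 || cfg$freeze_factor > 1) {
    stop("`freeze_factor` must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$heading_persistence < 0 || cfg$heading_persistence >= 1) {
    stop("`heading_persistence` must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$cohesion_weight < 0) stop("`cohesion_weight` must be >= 0", call. = FALSE)
  if (cfg$event_speed_multiplier <= 0) {
    stop("`event_speed_multiplier` must be > 0", call. = FALSE)
  }
  if (!is.na(cfg$event_time)) {
    if (cfg$event_time < 0 ||
        cfg$event_time + cfg$event_duration > cfg$recording_duration) {
      stop("event window must lie within the recording", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d fish, %gx%g px, %g fps, recording %g s (seed %d)\n",
    x$n_fish, x$arena_width, x$arena_height, x$fps,
    x$recording_duration, x$seed
  ))
  invisible(x)
}

# total number of simulated frames in the recording
n_recording_frames <- function(cfg) floor(cfg$fps * cfg$recording_duration)

# frames per analysis clip (5040 at the defaults)
n_clip_frames <- function(cfg) floor(cfg$fps * cfg$clip_duration)
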