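# -- deterministic noise bundle ------------------------------------------------
# All randomness of a simulation is drawn here, in a fixed order, from the
# config seed. Re-generating the bundle from the same config is how
# apply_event() re-integrates the event window bit-identically.
sim_noise <- function(cfg) {
  n <- cfg$n_fish
  nf <- n_recording_frames(cfg)
  set.seed(cfg$seed)
  list(
    bold = exp(stats::rnorm(n, 0, cfg$boldness_sd)),
    px0 = stats::runif(n, 0.3 * cfg$arena_width, 0.7 * cfg$arena_width),
    py0 = stats::runif(n, 0.3 * cfg$arena_height, 0.7 * cfg$arena_height),
    th0 = stats::runif(n, 0, 2 * pi),
    moving0 = stats::runif(1),
    ustate = stats::runif(nf),
    nx = matrix(stats::rnorm(nf * n, 0, cfg$noise_sd), nf, n),
    ny = matrix(stats::rnorm(nf * n, 0, cfg$noise_sd), nf, n)
  )
}

# long-run fraction of time the group spends in its moving state
activity_fraction <- function(cfg, bold) {
  min(cfg$activity_max * (1 - exp(-cfg$n_fish / cfg$activity_scale)) *
        mean(bold), 0.95)
}

# Integrate frames `frames` (a contiguous 1-based index range) starting from
# `state` = list(px, py, ux, uy, moving). `speed_mult`/`coh_mult` are
# per-frame multiplier vectors aligned with `frames`; `force_move` marks
# frames at which the group is startled into its moving state.
run_segment <- function(cfg, noise, state, frames,
                        speed_mult = NULL, coh_mult = NULL,
                        force_move = NULL) {
  n <- cfg$n_fish
  W <- cfg$arena_width
  H <- cfg$arena_height
  m <- length(frames)
  if (is.null(speed_mult)) speed_mult <- rep(1, m)
  if (is.null(coh_mult)) coh_mult <- rep(1, m)
  if (is.null(force_move)) force_move <- rep(FALSE, m)

  f_move <- activity_fraction(cfg, noise$bold)
  p_off <- 1 / max(cfg$bout_length * cfg$fps, 1)
  p_on <- p_off * f_move / (1 - f_move)

  speed0 <- cfg$base_speed * noise$bold
  if (n == 1L) speed0 <- speed0 * cfg$freeze_factor

  px <- state$px; py <- state$py
  ux <- state$ux; uy <- state$uy
  moving <- state$moving

  X <- matrix(0, m, n); Y <- matrix(0, m, n)
  UX <- matrix(0, m, n); UY <- matrix(0, m, n)
  MOV <- logical(m)

  for (i in seq_len(m)) {
    f <- frames[i]
    u <- noise$ustate[f]
    moving <- if (moving) u >= p_off else u < p_on
    if (force_move[i]) moving <- TRUE

    if (n >= 2L) {
      gx <- mean(px); gy <- mean(py)
      mx <- mean(ux); my <- mean(uy)
      coh <- cfg$cohesion_weight * coh_mult[i]
      dx <- cfg$heading_persistence * ux + cfg$alignment_weight * mx +
        coh * (gx - px) + noise$nx[f, ]
      dy <- cfg$heading_persistence * uy + cfg$alignment_weight * my +
        coh * (gy - py) + noise$ny[f, ]
    } else {
      dx <- cfg$heading_persistence * ux + noise$nx[f, ]
      dy <- cfg$heading_persistence * uy + noise$ny[f, ]
    }
    nrm <- sqrt(dx * dx + dy * dy)
    nrm[nrm < 1e-12] <- 1
    ux <- dx / nrm; uy <- dy / nrm

    sp <- speed0 * speed_mult[i]
    if (!moving) sp <- sp * cfg$hover_speed_frac
    px <- px + sp * ux
    py <- py + sp * uy

    # reflecting tank walls
    out <- px < 0;  px[out] <- -px[out];               ux[out] <- -ux[out]
    out <- px >= W; px[out] <- 2 * W - px[out] - 1e-9; ux[out] <- -ux[out]
    out <- py < 0;  py[out] <- -py[out];               uy[out] <- -uy[out]
    out <- py >= H; py[out] <- 2 * H - py[out] - 1e-9; uy[out] <- -uy[out]

    X[i, ] <- px; Y[i, ] <- py
    UX[i, ] <- ux; UY[i, ] <- uy
    MOV[i] <- moving
  }
  list(X = X, Y = Y, UX = UX, UY = UY, MOV = MOV,
       state = list(px = px, py = py, ux = ux, uy = uy, moving = moving))
}

initial_state <- function(cfg, noise) {
  f_move <- activity_fraction(cfg, noise$bold)
  list(px = noise$px0, py = noise$py0,
       ux = cos(noise$th0), uy = sin(noise$th0),
       moving = noise$moving0 < f_move)
}

new_shoal_trace <- function(cfg, X, Y, UX, UY, MOV, event_frame = NA_integer_) {
  nf <- nrow(X)
  VX <- X - rbind(X[1, , drop = FALSE], X[-nf, , drop = FALSE])
  VY <- Y - rbind(Y[1, , drop = FALSE], Y[-nf, , drop = FALSE])
  structure(
    list(x = X, y = Y, vx = VX, vy = VY,
         event_frame_index = event_frame, config = cfg),
    heading_x = UX, heading_y = UY, moving = MOV,
    class = "shoal_trace"
  )
}

#' Simulate a shoal of fish in its basal (undisturbed) state
#'
#' Runs the cohesive intermittent correlated random walk described in
#' [sim_config()] for the whole recording. The returned trace holds per-fish,
#' per-frame positions and velocities (pixels and pixels/frame); the
#' disturbance, if any, is applied afterwards by [apply_event()].
#'
#' @param cfg a [sim_config()] object.
#' @return A `shoal_trace`: list with `x`, `y`, `vx`, `vy` (frames x fish
#'   matrices), `event_frame_index` (`NA` here) and `config`.
#' @examples
#' tr <- simulate_shoal(sim_config(n_fish = 5, recording_duration = 10, seed = 1))
#' dim(tr$x)  # 240 frames x 5 fish
#' @export
simulate_shoal <- function(cfg) {
  validate_sim_config(cfg)
  noise <- sim_noise(cfg)
  seg <- run_segment(cfg, noise, initial_state(cfg, noise),
                     seq_len(n_recording_frames(cfg)))
  new_shoal_trace(cfg, seg$X, seg$Y, seg$UX, seg$UY, seg$MOV)
}

#' Apply the disturbance (schooling burst) to a simulated trace
#'
#' From `event_time` on, for `event_duration` seconds, swim speeds are
#' multiplied by `event_speed_multiplier` and centroid attraction by
#' `event_cohesion_multiplier`; when either multiplier exceeds 1 the group is
#' also startled into its moving state at onset. The segment from the event
#' frame onwards is re-integrated from the stored fish state using the same
#' seeded noise, so multipliers of exactly 1 reproduce the input trace
#' bit-identically, and frames before the event are untouched.
#'
#' @param trace a `shoal_trace` from [simulate_shoal()].
#' @param cfg the same [sim_config()], with `event_time` set.
#' @return A `shoal_trace` with `event_frame_index` set.
#' @export
apply_event <- function(trace, cfg) {
  stopifnot(inherits(trace, "shoal_trace"))
  if (is.na(cfg$event_time)) stop("`event_time` is not set", call. = FALSE)
  nf <- nrow(trace$x)
  e <- floor(cfg$event_time * cfg$fps) + 1L
  dur <- floor(cfg$event_duration * cfg$fps)
  if (e < 1L || e > nf || (e + dur - 1L) > nf) {
    stop("event window lies outside the recording", call. = FALSE)
  }
  trace$event_frame_index <- e
  if (dur == 0L) {
    return(trace)
  }

  noise <- sim_noise(cfg)
  state <- if (e == 1L) {
    initial_state(cfg, noise)
  } else {
    list(px = trace$x[e - 1L, ], py = trace$y[e - 1L, ],
         ux = attr(trace, "heading_x")[e - 1L, ],
         uy = attr(trace, "heading_y")[e - 1L, ],
         moving = attr(trace, "moving")[e - 1L])
  }
  frames <- e:nf
  in_win <- frames < e + dur
  sm <- ifelse(in_win, cfg$event_speed_multiplier, 1)
  cm <- ifelse(in_win, cfg$event_cohesion_multiplier, 1)
  burst <- cfg$event_speed_multiplier > 1 || cfg$event_cohesion_multiplier > 1
  fm <- in_win & burst
  seg <- run_segment(cfg, noise, state, frames, sm, cm, fm)

  X <- trace$x; Y <- trace$y
  UX <- attr(trace, "heading_x"); UY <- attr(trace, "heading_y")
  MOV <- attr(trace, "moving")
  X[frames, ] <- seg$X; Y[frames, ] <- seg$Y
  UX[frames, ] <- seg$UX; UY[frames, ] <- seg$UY
  MOV[frames] <- seg$MOV
  new_shoal_trace(cfg, X, Y, UX, UY, MOV, event_frame = e)
}

#' Group-centroid trajectory of a simulated trace
#'
#' The per-frame unweighted mean of the true fish positions: the simulator's
#' ground truth against which image-based extraction is judged.
#'
#' @param trace a `shoal_trace`.
#' @param frames optional frame indices to keep.
#' @return A `trajectory_series` (see [trajectory_series()]).
#' @export
true_centroid <- function(trace, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(nrow(trace$x))
  trajectory_series(
    frame = seq_along(frames),
    x = rowMeans(trace$x[frames, , drop = FALSE]),
    y = rowMeans(trace$y[frames, , drop = FALSE]),
    source = "synthetic"
  )
}

#' Render a trace as binary frames
#'
#' Draws each fish as a filled disk of `fish_radius` pixels on a black
#' 640 x 480 background (one matrix per frame, rows = image y, columns =
#' image x, values 0/1). Overlapping fish merge into one connected
#' component, exactly as in thresholded video of a dense shoal. Pixel
#' centers sit at (column - 0.5, row - 0.5) so rasterized centroids match
#' simulated positions to sub-pixel accuracy.
#'
#' @param trace a `shoal_trace`.
#' @param cfg its [sim_config()].
#' @param frames which frames to render (default: all; rendering full clips
#'   is memory-hungry, so subset deliberately).
#' @return A list of `arena_height` x `arena_width` numeric matrices.
#' @export
render_frames <- function(trace, cfg, frames = NULL) {
  r <- cfg$fish_radius
  if (r < 1) stop("`fish_radius` must be >= 1", call. = FALSE)
  if (2 * r >= min(cfg$arena_width, cfg$arena_height)) {
    stop("`fish_radius` too large: a disk would exceed the arena",
         call. = FALSE)
  }
  if (is.null(frames)) frames <- seq_len(nrow(trace$x))
  W <- as.integer(cfg$arena_width)
  H <- as.integer(cfg$arena_height)
  lapply(frames, function(f) {
    img <- matrix(0, H, W)
    for (i in seq_len(ncol(trace$x))) {
      cx <- trace$x[f, i]; cy <- trace$y[f, i]
      cols <- max(1L, floor(cx - r + 0.5)):min(W, ceiling(cx + r + 0.5))
      rows <- max(1L, floor(cy - r + 0.5)):min(H, ceiling(cy + r + 0.5))
      dx2 <- (cols - 0.5 - cx)^2
      dy2 <- (rows - 0.5 - cy)^2
      img[rows, cols][outer(dy2, dx2, "+") <= r^2] <- 1
    }
    img
  })
}

#' Cut a recording into basal and event analysis clips
#'
#' Reproduces the monitoring protocol: from one recording containing a
#' disturbance, take `n_basal` disjoint 3.5-min basal clips before the event
#' and one 3.5-min response clip starting at the event. Basal clip placement
#' is drawn (seeded) among the admissible positions, mimicking the
#' "arbitrary" choice of basal windows. Each clip's trajectory is the true
#' group centroid of the simulated fish.
#'
#' @param cfg a [sim_config()] with `event_time` set.
#' @param n_basal number of basal clips (default 3).
#' @return A list with one element per clip: `list(clip_type, trajectory)`,
#'   `clip_type` in `"basal1"..."basalN"`, `"event"`.
#' @examples
#' clips <- make_clipset(sim_config(
#'   n_fish = 2, clip_duration = 2, event_duration = 1,
#'   recording_duration = 10, event_time = 7, seed = 1))
#' vapply(clips, `[[`, "", "clip_type")
#' @export
make_clipset <- function(cfg, n_basal = 3) {
  validate_sim_config(cfg)
  if (is.na(cfg$event_time)) stop("`event_time` is not set", call. = FALSE)
  nf <- n_recording_frames(cfg)
  cl <- n_clip_frames(cfg)
  e <- floor(cfg$event_time * cfg$fps) + 1L
  if (e + cl - 1L > nf) {
    stop("recording too short for a full post-event clip", call. = FALSE)
  }
  slack <- (e - 1L) - n_basal * cl
  if (n_basal > 0 && slack < 0) {
    stop("recording cannot hold ", n_basal,
         " disjoint basal clips before the event", call. = FALSE)
  }

  trace <- simulate_shoal(cfg)
  trace <- apply_event(trace, cfg)
  cent_x <- rowMeans(trace$x)
  cent_y <- rowMeans(trace$y)

  clip_of <- function(start, type) {
    idx <- start:(start + cl - 1L)
    list(clip_type = type,
         trajectory = trajectory_series(seq_len(cl), cent_x[idx], cent_y[idx],
                                        source = "synthetic"))
  }

  clips <- list()
  if (n_basal > 0) {
    set.seed(cfg$seed + 7919L)  # clip placement stream, separate from motion
    extra <- sort(sample.int(slack + 1L, n_basal, replace = TRUE) - 1L)
    starts <- (seq_len(n_basal) - 1L) * cl + extra + 1L
    clips <- lapply(seq_len(n_basal), function(i) {
      clip_of(starts[i], paste0("basal", i))
    })
  }
  c(clips, list(clip_of(e, "event")))
}

#' Synthetic entropy-versus-fish-number data from a power law
#'
#' Draws replicate SE values from `se = a * n^b + c + N(0, noise_sd)`, the
#' functional form used to characterize Shannon entropy against group size.
#' Used for fit-recovery and coverage testing.
#'
#' @param a,b,c power-law coefficients.
#' @param noise_sd Gaussian noise sd in entropy units (0 for noiseless).
#' @param n_values fish counts (all >= 1; `n^b` is undefined at 0 for b < 0).
#' @param replicates replicate draws per count.
#' @param seed RNG seed.
#' @return A tibble with columns `n`, `se`.
#' @examples
#' generate_se_curve_data(-4.17, -0.49, 5.40, 0, n_values = 1, replicates = 1)
#' @export
generate_se_curve_data <- function(a, b, c, noise_sd, n_values,
                                   replicates = 1, seed = 1) {
  if (any(n_values <= 0)) {
    stop("`n_values` must be positive fish counts", call. = FALSE)
  }
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  n <- rep(n_values, each = replicates)
  mu <- a * n^b + c
  se <- if (noise_sd > 0) {
    set.seed(seed)
    mu + stats::rnorm(length(mu), 0, noise_sd)
  } else {
    mu
  }
  tibble::tibble(n = n, se = se)
}
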