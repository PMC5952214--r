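# Shared fixtures and independent oracles.

# Small, fast simulation config for structural tests.
quick_cfg <- function(n_fish, seed = 1, ...) {
  sim_config(n_fish = n_fish, recording_duration = 10, seed = seed, ...)
}

# Independent brute-force Shannon entropy: explicit counting loop over bins,
# no shared code with shannon_entropy().
brute_entropy <- function(x, breaks, base = 2) {
  nb <- length(breaks) - 1
  counts <- integer(nb)
  for (v in x) {
    for (j in seq_len(nb)) {
      hi_ok <- if (j == nb) v <= breaks[j + 1] else v < breaks[j + 1]
      if (v >= breaks[j] && hi_ok) {
        counts[j] <- counts[j] + 1
        break
      }
    }
  }
  h <- 0
  for (cnt in counts) {
    if (cnt > 0) {
      p <- cnt / length(x)
      h <- h - p * log(p)
    }
  }
  h / log(base)
}

# A fake shoal trace with prescribed positions (frames x fish matrices),
# enough for render_frames() and true_centroid().
fake_trace <- function(X, Y, cfg) {
  structure(list(x = X, y = Y, vx = X * 0, vy = Y * 0,
                 event_frame_index = NA_integer_, config = cfg),
            class = "shoal_trace")
}

# Mean per-frame step length of every fish in a trace.
mean_step <- function(trace) {
  nf <- nrow(trace$x)
  dx <- trace$x[-1, , drop = FALSE] - trace$x[-nf, , drop = FALSE]
  dy <- trace$y[-1, , drop = FALSE] - trace$y[-nf, , drop = FALSE]
  mean(sqrt(dx^2 + dy^2))
}

# Daily summaries drawn from Gaussian SE channels (healthy-system stream).
gaussian_summaries <- function(days, mu_basal, sd_basal, mu_event, sd_event,
                               n_fish = 13, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    experiment = "sim", tank = "1", day = seq_len(days),
    n_fish = as.integer(n_fish),
    basal_mean = rnorm(days, mu_basal, sd_basal),
    basal_sd = 0.1,
    event_se = rnorm(days, mu_event, sd_event)
  )
}
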