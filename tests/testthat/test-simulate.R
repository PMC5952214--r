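test_that("config validation rejects impossible set-ups", {
  expect_error(sim_config(n_fish = 0), "n_fish")
  expect_error(sim_config(n_fish = 2, base_speed = -1), "base_speed")
  expect_error(sim_config(n_fish = 2, arena_width = 0), "dimensions")
  expect_error(sim_config(n_fish = 2, freeze_factor = 0), "freeze_factor")
  expect_error(sim_config(n_fish = 2, event_time = 835, event_duration = 10),
               "event window")
})

test_that("simulation is deterministic and stays inside the arena", {
  for (n in c(1, 7)) {
    cfg <- quick_cfg(n, seed = 11)
    a <- simulate_shoal(cfg)
    b <- simulate_shoal(cfg)
    expect_identical(a$x, b$x)
    expect_identical(a$y, b$y)
    expect_true(all(a$x >= 0 & a$x < cfg$arena_width))
    expect_true(all(a$y >= 0 & a$y < cfg$arena_height))
    expect_equal(nrow(a$x), floor(cfg$fps * cfg$recording_duration))
    expect_equal(ncol(a$x), n)
  }
})

test_that("a single fish barely moves compared to a small shoal", {
  s1 <- mean_step(simulate_shoal(quick_cfg(1, seed = 7)))
  s5 <- mean_step(simulate_shoal(quick_cfg(5, seed = 7)))
  expect_lt(s1, 0.15 * s5)
})

test_that("without coupling terms, fish move independently", {
  # constant speed (no shared burst/hover modulation) isolates the
  # directional coupling terms, which are switched off here
  cfg <- sim_config(6, recording_duration = 60, seed = 3,
                    cohesion_weight = 0, alignment_weight = 0,
                    hover_speed_frac = 1)
  tr <- simulate_shoal(cfg)
  nf <- nrow(tr$x)
  steps <- tr$x[-1, ] - tr$x[-nf, ]
  cors <- cor(steps)
  off_diag <- abs(cors[upper.tri(cors)])
  expect_lt(max(off_diag), 0.1)
})

test_that("the disturbance is a speed burst confined to its window", {
  cfg <- quick_cfg(13, seed = 5, event_time = 5, event_duration = 2)
  tr <- simulate_shoal(cfg)

  # multiplier exactly 1 and unchanged cohesion: identity
  cfg_id <- cfg
  cfg_id$event_speed_multiplier <- 1
  cfg_id$event_cohesion_multiplier <- 1
  tr_id <- apply_event(tr, cfg_id)
  expect_identical(tr_id$x, tr$x)
  expect_identical(tr_id$y, tr$y)
  expect_equal(tr_id$event_frame_index, 5 * cfg$fps + 1)

  # real burst: mean speed in window >= 2x pre-event mean speed
  tr_ev <- apply_event(tr, cfg)
  e <- tr_ev$event_frame_index
  win <- e:(e + 2 * cfg$fps - 1)
  sp <- sqrt(tr_ev$vx^2 + tr_ev$vy^2)
  expect_gte(mean(sp[win, ]), 2 * mean(sp[2:(e - 1), ]))
  # pre-event frames untouched
  expect_identical(tr_ev$x[1:(e - 1), ], tr$x[1:(e - 1), ])

  # zero-length window at the last frame is a valid no-op
  cfg0 <- quick_cfg(13, seed = 5)
  cfg0$event_time <- (nrow(tr$x) - 1) / cfg0$fps
  cfg0$event_duration <- 0
  tr0 <- apply_event(tr, cfg0)
  expect_identical(tr0$x, tr$x)

  # window outside the recording
  cfg_bad <- quick_cfg(13, seed = 5)
  cfg_bad$event_time <- 9.9
  cfg_bad$event_duration <- 5
  expect_error(apply_event(tr, cfg_bad), "outside the recording")
  expect_error(apply_event(tr, quick_cfg(13, seed = 5)), "event_time")
})

test_that("clip sets follow the three-basal-plus-event protocol", {
  cfg <- sim_config(n_fish = 2, clip_duration = 2, recording_duration = 10,
                    event_time = 7, event_duration = 1, seed = 2)
  clips <- make_clipset(cfg)
  expect_length(clips, 4)
  expect_equal(vapply(clips, `[[`, "", "clip_type"),
               c("basal1", "basal2", "basal3", "event"))
  for (cl in clips) {
    expect_s3_class(cl$trajectory, "trajectory_series")
    expect_equal(nrow(cl$trajectory), 2 * cfg$fps)
  }
  # identical config + seed => identical clips
  clips2 <- make_clipset(cfg)
  expect_identical(clips[[1]]$trajectory$x, clips2[[1]]$trajectory$x)

  # defaults give 5040-frame clips (24 fps x 3.5 min)
  expect_equal(floor(sim_config(n_fish = 1)$fps *
                       sim_config(n_fish = 1)$clip_duration), 5040)

  # no room for basal windows before an immediate event
  cfg_bad <- sim_config(n_fish = 2, clip_duration = 2,
                        recording_duration = 10, event_time = 0,
                        event_duration = 1, seed = 2)
  expect_error(make_clipset(cfg_bad), "basal")

  # n_basal = 0: event clip only
  clips0 <- make_clipset(cfg, n_basal = 0)
  expect_length(clips0, 1)
  expect_equal(clips0[[1]]$clip_type, "event")
})

test_that("power-law curve data generator matches direct evaluation", {
  d <- generate_se_curve_data(-4.17, -0.49, 5.40, 0, n_values = 1,
                              replicates = 1)
  expect_equal(d$se, 1.23, tolerance = 1e-12)

  # noiseless draws ignore the seed
  d1 <- generate_se_curve_data(2, -1, 3, 0, n_values = 1:5, seed = 1)
  d2 <- generate_se_curve_data(2, -1, 3, 0, n_values = 1:5, seed = 99)
  expect_identical(d1, d2)

  # a = 0 gives the constant offset
  expect_true(all(generate_se_curve_data(0, -0.5, 4.2, 0, 1:10)$se == 4.2))

  expect_error(generate_se_curve_data(1, -1, 0, 0, n_values = c(0, 1)),
               "positive")

  # noisy draws are seeded and centred on the curve
  dn <- generate_se_curve_data(-4.17, -0.49, 5.40, 0.1,
                               n_values = c(1, 13, 25, 50),
                               replicates = 50, seed = 4)
  expect_equal(nrow(dn), 200)
  mu <- -4.17 * 13^-0.49 + 5.40
  expect_lt(abs(mean(dn$se[dn$n == 13]) - mu), 0.05)
})
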