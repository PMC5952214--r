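test_that("segmentation finds rendered disks with sub-pixel centers", {
  cfg <- sim_config(n_fish = 1, recording_duration = 1, seed = 1)

  # blank frame: empty element list, not an error
  blank <- matrix(0, 480, 640)
  expect_equal(nrow(segment_frame(blank)), 0)

  # wrong dimensions refused
  expect_error(segment_frame(matrix(0, 100, 100)), "expected 480 x 640")

  # one disk at a known position (opening disabled to judge raw raster area)
  tr <- fake_trace(matrix(100, 1, 1), matrix(200, 1, 1), cfg)
  img <- render_frames(tr, cfg, frames = 1)[[1]]
  el <- segment_frame(img, opening_size = 0)
  expect_equal(nrow(el), 1)
  expect_lt(abs(el$x - 100), 0.5)
  expect_lt(abs(el$y - 200), 0.5)
  expect_lt(abs(el$area - pi * 3^2) / (pi * 3^2), 0.15)

  # two disjoint disks
  tr2 <- fake_trace(matrix(c(100, 300), 1, 2), matrix(c(200, 350), 1, 2), cfg)
  el2 <- segment_frame(render_frames(tr2, cfg, frames = 1)[[1]],
                       opening_size = 0)
  expect_equal(nrow(el2), 2)
  expect_true(all(abs(el2$area - pi * 9) / (pi * 9) < 0.15))

  # two fish far apart across frames: centers recovered within 1 px
  X <- cbind(seq(100, 120, length.out = 10), seq(400, 420, length.out = 10))
  Y <- cbind(seq(200, 210, length.out = 10), seq(100, 110, length.out = 10))
  cfg2 <- sim_config(n_fish = 2, recording_duration = 1, seed = 1)
  els <- segment_frames(render_frames(fake_trace(X, Y, cfg2), cfg2),
                        opening_size = 0)
  for (f in seq_along(els)) {
    expect_equal(nrow(els[[f]]), 2)
    got <- els[[f]][order(els[[f]]$x), ]
    expect_lt(max(abs(got$x - X[f, ]), abs(got$y - Y[f, ])), 1)
  }
})

test_that("rendering validates the fish radius", {
  cfg <- sim_config(n_fish = 1, recording_duration = 1, seed = 1)
  tr <- simulate_shoal(cfg)
  cfg$fish_radius <- 0.5
  expect_error(render_frames(tr, cfg), ">= 1")
  cfg$fish_radius <- 400
  expect_error(render_frames(tr, cfg), "exceed the arena")
})

test_that("naive centroid is the per-frame mean with gap filling", {
  one <- lapply(1:5, function(f) tibble::tibble(x = f, y = 2 * f, area = 10))
  tr <- naive_centroid(one)
  expect_equal(tr$x, 1:5)
  expect_equal(tr$y, 2 * (1:5))
  expect_equal(attr(tr, "source"), "naive")

  two <- lapply(1:4, function(f) {
    tibble::tibble(x = c(0, 10), y = c(0, 10), area = c(5, 5))
  })
  tr2 <- naive_centroid(two)
  expect_true(all(tr2$x == 5) && all(tr2$y == 5))

  # empty middle frame carries the last valid position forward
  gap <- two
  gap[[3]] <- tibble::tibble(x = numeric(), y = numeric(), area = numeric())
  tr3 <- naive_centroid(gap)
  expect_equal(nrow(tr3), 4)
  expect_equal(tr3$x[3], tr3$x[2])

  empty <- list(tibble::tibble(x = numeric(), y = numeric(),
                               area = numeric()))
  expect_error(naive_centroid(empty), "all frames")
})

test_that("k-means trajectory equals the naive one for clean stable scenes", {
  els <- lapply(1:20, function(f) {
    tibble::tibble(x = c(50, 100, 150) + f, y = c(30, 60, 90) + 0.5 * f,
                   area = 10)
  })
  km <- kmeans_centroid_trajectory(els)
  nv <- naive_centroid(els)
  expect_equal(km$x, nv$x, tolerance = 1e-6)
  expect_equal(km$y, nv$y, tolerance = 1e-6)

  # single element per frame: the element path itself
  single <- lapply(1:10, function(f) tibble::tibble(x = f, y = f, area = 5))
  km1 <- kmeans_centroid_trajectory(single)
  expect_equal(km1$x, 1:10, tolerance = 1e-9)

  expect_error(
    kmeans_centroid_trajectory(c(
      list(tibble::tibble(x = numeric(), y = numeric(), area = numeric())),
      single
    )),
    "anchor frame"
  )
})

test_that("k-means smoothing beats the naive mean under spurious blobs", {
  cfg <- quick_cfg(5, seed = 21)
  tr <- simulate_shoal(cfg)
  nf <- nrow(tr$x)
  set.seed(99)
  noisy_frames <- sample(nf, round(0.05 * nf))
  els <- lapply(seq_len(nf), function(f) {
    e <- tibble::tibble(x = tr$x[f, ], y = tr$y[f, ], area = 28)
    if (f %in% noisy_frames) {
      e <- rbind(e, tibble::tibble(x = runif(1, 0, 640),
                                   y = runif(1, 0, 480), area = 5))
    }
    e
  })
  truth <- true_centroid(tr)
  km <- kmeans_centroid_trajectory(els)
  nv <- naive_centroid(els)
  err_km <- var(km$x - truth$x) + var(km$y - truth$y)
  err_nv <- var(nv$x - truth$x) + var(nv$y - truth$y)
  expect_lt(err_km, err_nv)
})

test_that("simulate -> render -> segment -> k-means recovers the centroid", {
  cfg <- sim_config(n_fish = 5, recording_duration = 5, seed = 3)
  tr <- simulate_shoal(cfg)
  frames <- 1:100
  els <- segment_frames(render_frames(tr, cfg, frames = frames))
  km <- kmeans_centroid_trajectory(els)
  truth <- true_centroid(tr, frames = frames)
  rmse <- sqrt(mean((km$x - truth$x)^2 + (km$y - truth$y)^2))
  expect_lt(rmse, 1)
  expect_equal(nrow(km), length(frames))
})

test_that("centroid estimators are translation-equivariant", {
  set.seed(42)
  els <- lapply(1:30, function(f) {
    tibble::tibble(x = runif(3, 100, 200), y = runif(3, 100, 200), area = 10)
  })
  shift <- function(es, dx, dy) {
    lapply(es, function(e) tibble::tibble(x = e$x + dx, y = e$y + dy,
                                          area = e$area))
  }
  for (fn in list(naive_centroid, kmeans_centroid_trajectory)) {
    base <- fn(els)
    moved <- fn(shift(els, 12.5, -7.25))
    expect_equal(moved$x, base$x + 12.5, tolerance = 1e-9)
    expect_equal(moved$y, base$y - 7.25, tolerance = 1e-9)
  }
})

test_that("z-score normalization matches hand computation and is idempotent", {
  toy <- trajectory_series(1:2, c(0, 640), c(0, 480))
  z <- zscore(toy)
  expect_equal(z$x, c(-0.7071068, 0.7071068), tolerance = 1e-6)
  expect_true(attr(z, "normalized"))
  expect_equal(mean(z$x), 0, tolerance = 1e-9)
  expect_equal(sd(z$y), 1, tolerance = 1e-9)

  z2 <- zscore(z)
  expect_equal(z2$x, z$x, tolerance = 1e-9)

  flat <- trajectory_series(1:5, 1:5, rep(2, 5))
  expect_error(zscore(flat), "y axis")
})

test_that("frame PNG round trip preserves binary frames", {
  cfg <- sim_config(n_fish = 2, recording_duration = 1, seed = 8)
  tr <- simulate_shoal(cfg)
  frames <- render_frames(tr, cfg, frames = 1:3)
  dir <- withr::local_tempdir()
  write_frames(frames, dir)
  back <- read_frames(dir)
  expect_length(back, 3)
  expect_equal(back[[1]], frames[[1]], tolerance = 1e-6)
})
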