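test_that("spot detection finds planted Gaussians with sub-pixel accuracy", {
  pos <- cbind(c(20, 20, 60, 70, 45), c(20, 70, 30, 75, 50))
  f <- make_spot_frame(pos, amplitude = 100, sigma = 1.5, noise_sd = 10,
                       seed = 2)
  sp <- detect_spots(f)
  expect_equal(nrow(sp), 5)
  for (i in 1:5) {
    expect_lt(min(sqrt((sp$row - pos[i, 1])^2 + (sp$col - pos[i, 2])^2)), 0.5)
  }
  expect_true(all(sp$peak_intensity > sp$background))
  expect_true(all(sp$circularity <= 1))
})

test_that("spot detection rejects noise, thin shapes and saturated frames", {
  set.seed(3)
  noise <- matrix(rnorm(96 * 96, 100, 10), 96, 96)
  expect_equal(nrow(detect_spots(noise, k_sigma = 5)), 0)
  # a 1x9 line is excluded by the circularity filter
  set.seed(4)
  fl <- matrix(rnorm(96 * 96, 100, 10), 96, 96)
  fl[48, 40:48] <- fl[48, 40:48] + 150
  expect_equal(nrow(detect_spots(fl)), 0)
  expect_error(detect_spots(matrix(65535, 32, 32)), "saturated|flat")
})

test_that("spot detection is invariant to a constant intensity offset", {
  pos <- cbind(c(25, 60), c(40, 70))
  f <- make_spot_frame(pos, seed = 6)
  a <- detect_spots(f)
  b <- detect_spots(f + 123.4)
  expect_equal(a$row, b$row)
  expect_equal(a$col, b$col)
  expect_equal(a$area, b$area)
  expect_equal(a$intensity, b$intensity, tolerance = 1e-8)
})

test_that("doubling the PSF sigma enlarges detected spots superlinearly", {
  pos <- cbind(c(20, 20, 60, 70, 45), c(20, 70, 30, 75, 50))
  a1 <- mean(detect_spots(make_spot_frame(pos, sigma = 1.3, seed = 5))$area)
  a2 <- mean(detect_spots(make_spot_frame(pos, sigma = 2.6, seed = 5))$area)
  expect_gt(a2 / a1, 2.5)  # threshold-crossing area scales ~ sigma^2
  expect_lt(a2 / a1, 4.5)
})

test_that("greedy linking joins, gaps and splits tracks as specified", {
  mk <- function(rows, cols) data.frame(row = rows, col = cols,
                                        area = rep(9, length(rows)),
                                        circularity = rep(0.8, length(rows)),
                                        peak_intensity = rep(500, length(rows)),
                                        background = rep(100, length(rows)),
                                        intensity = rep(1000, length(rows)))
  # two stationary spots 20 px apart over 10 frames -> two 10-long tracks
  frames <- replicate(10, mk(c(10, 30), c(10, 10)), simplify = FALSE)
  tr <- link_tracks(frames)
  expect_equal(length(tr), 2)
  expect_equal(vapply(tr, nrow, 1L), c(10L, 10L))
  # one spot moving 1 px/frame stays a single unbroken track
  frames2 <- lapply(1:10, function(f) mk(10 + f, 20))
  tr2 <- link_tracks(frames2, max_displacement = 3)
  expect_equal(length(tr2), 1)
  expect_equal(nrow(tr2[[1]]), 10)
  # a gap longer than max_gap splits the track in two
  present <- c(1:4, 8:10)  # 3 missing frames, max_gap = 2
  frames3 <- lapply(1:10, function(f) if (f %in% present) mk(50, 50) else mk(numeric(0), numeric(0)))
  tr3 <- link_tracks(frames3, max_gap = 2)
  expect_equal(length(tr3), 2)
  # but a gap of exactly max_gap frames is bridged
  present4 <- c(1:4, 7:10)
  frames4 <- lapply(1:10, function(f) if (f %in% present4) mk(50, 50) else mk(numeric(0), numeric(0)))
  expect_equal(length(link_tracks(frames4, max_gap = 2)), 1)
})

test_that("stationarity gate separates docked from drifting vesicles", {
  docked <- make_track(rep(1000, 20), jitter = 0)
  expect_true(stationarity(docked, window_frames = 5, max_drift_px = 3))
  drifting <- data.frame(frame = 1:10, row = 2 * (1:10), col = 50,
                         intensity = 1000)
  expect_false(stationarity(drifting, window_frames = 5, max_drift_px = 3))
  # Brownian jitter with 0.1 px steps is essentially always stationary
  for (seed in 1:10) {
    tr <- make_track(rep(1000, 30), jitter = 0.1, seed = seed)
    expect_true(stationarity(tr, window_frames = 5, max_drift_px = 3))
  }
  # too-short track cannot be assessed
  expect_false(stationarity(docked[1:3, ], window_frames = 5))
})

test_that("fusion classifier fires on a two-frame collapse of a docked vesicle", {
  set.seed(8)
  I <- c(rnorm(39, 1000, 5), 500, 0, 0, 0)
  tr <- make_track(I, jitter = 0.05)
  fe <- detect_fusion(tr)
  expect_false(is.null(fe))
  expect_equal(fe$fusion_frame, 40)
  expect_gt(fe$drop_sd, 2.5)
})

test_that("fusion classifier ignores smooth photobleaching and moving drops", {
  # exponential photobleaching: monotone smooth decay, no abrupt step
  set.seed(9)
  bleach <- 1000 * exp(-0.01 * (0:79)) + rnorm(80, 0, 2)
  expect_null(detect_fusion(make_track(bleach, jitter = 0.05)))
  # the same abrupt drop on a laterally moving vesicle is gated out
  I <- c(rep(1000, 39), 500, 0, 0)
  moving <- data.frame(frame = seq_along(I), row = 2 * seq_along(I),
                       col = 30, intensity = I)
  expect_null(detect_fusion(moving))
  # affine (linear-in-time) decay never triggers, whatever the slope
  for (slope in c(0.5, 2, 10, 50, 200)) {
    I <- 10000 - slope * (0:49)
    expect_null(detect_fusion(make_track(I, jitter = 0)),
                label = paste("slope", slope))
  }
})

test_that("event counting recovers planted fusions and rejects controls", {
  g <- gen_tirf_movie(tirf_sim_spec(seed = 5))
  expect_gte(nrow(g$truth), 20)
  ce <- count_events(g$movie, cell_count = 5)
  m <- match_events(ce$events, g$truth)
  expect_gte(m$tp / (m$tp + m$fn), 0.9)
  expect_gte(m$tp / (m$tp + m$fp), 0.9)
  expect_equal(ce$events_per_cell, ce$n_events / 5)
  # a movie with no planted fusions yields at most one false event
  g0 <- gen_tirf_movie(tirf_sim_spec(seed = 6, fusion_fraction = 0))
  expect_equal(nrow(g0$truth), 0)
  expect_lte(count_events(g0$movie)$n_events, 1)
  # a blank movie yields nothing
  set.seed(7)
  blank <- lapply(1:30, function(i) matrix(rnorm(96 * 96, 100, 10), 96, 96))
  expect_equal(count_events(blank)$n_events, 0)
})

test_that("event count is invariant under frame-wise 90-degree rotation", {
  g <- gen_tirf_movie(tirf_sim_spec(seed = 2, n_vesicles = 40L))
  rot90 <- function(m) t(m[nrow(m):1, ])
  rotated <- structure(list(frames = lapply(g$movie$frames, rot90),
                            frame_rate = 6.67, pixel_size = 0.16),
                       class = "tirf_movie")
  expect_equal(count_events(rotated)$n_events, count_events(g$movie)$n_events)
})

test_that("Pearson colocalization identities and null behaviour", {
  set.seed(10)
  a <- matrix(runif(64 * 64, 10, 200), 64, 64)
  expect_equal(pearson_colocalization(a, a), 1)
  expect_equal(pearson_colocalization(a, 300 - a), -1)
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(1e4), 100, 100)
    y <- matrix(rnorm(1e4), 100, 100)
    expect_lt(abs(pearson_colocalization(x, y)), 0.05)
  }
  # mask restricts the computation
  mask <- matrix(FALSE, 64, 64); mask[1:10, 1:10] <- TRUE
  b <- a; b[!mask] <- 0
  expect_equal(pearson_colocalization(a, b, mask), 1)
  expect_error(pearson_colocalization(a, matrix(5, 64, 64)), "zero-variance")
})

test_that("Manders coefficients hit closed-form fixture values", {
  m1 <- matrix(0, 10, 10); m1[1:5, ] <- 1
  expect_equal(manders_coefficients(m1, m1), c(M1 = 1, M2 = 1))
  m2 <- matrix(0, 10, 10); m2[6:10, ] <- 1
  expect_equal(manders_coefficients(m1, m2), c(M1 = 0, M2 = 0))
  # channel b covers exactly half of a's total intensity
  a <- matrix(0, 4, 4); a[1, 1] <- 30; a[1, 2] <- 50; a[2, 1] <- 80
  b <- matrix(0, 4, 4); b[1, 1] <- 1; b[1, 2] <- 1  # covers 30 + 50 = 80/160
  expect_equal(unname(manders_coefficients(a, b)["M1"]), 0.5)
  expect_error(manders_coefficients(a, matrix(0, 4, 4)), "all-zero")
})
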