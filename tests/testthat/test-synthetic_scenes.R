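test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- simulation_config(noise_sd = 50, poisson_noise = TRUE, seed = 99,
                           n_frames = 30L, stim_onset = 1,
                           event_schedule = data.frame(
                             spot = 1L, time_s = 0.5, class = "full_fusion"))
  a <- simulate_ldcv_movie(cfg)
  b <- simulate_ldcv_movie(cfg)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth$spots, b$truth$spots)

  s1 <- simulate_coloc_pair(1024L, 0.3, seed = 5L)
  s2 <- simulate_coloc_pair(1024L, 0.3, seed = 5L)
  expect_identical(s1$channelA, s2$channelA)

  # and the generator does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_ldcv_movie(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("a null scene is static except for bleaching, and truth is empty", {
  cfg <- simulation_config(n_spots = 5L, n_frames = 20L, bleach_tau = 1e9)
  sim <- simulate_ldcv_movie(cfg)
  expect_equal(nrow(sim$truth$events), 0L)
  for (t in 2:20)
    expect_equal(sim$movie$frames[, , t], sim$movie$frames[, , 1],
                 tolerance = 1e-6)
  # with finite bleaching frames decay monotonically at spot centers
  cfg2 <- simulation_config(n_spots = 5L, n_frames = 20L, bleach_tau = 50)
  sim2 <- simulate_ldcv_movie(cfg2)
  ctr <- round(as.numeric(sim2$truth$spots[1, c("row", "col")])) + 1L
  trace <- sim2$movie$frames[ctr[1], ctr[2], ]
  expect_true(all(diff(trace) < 0))
})

test_that("scheduled full fusion empties the spot center within 200 ms", {
  cfg <- simulation_config(event_schedule = data.frame(
    spot = 2L, time_s = 2, class = "full_fusion"))
  sim <- simulate_ldcv_movie(cfg)
  tr <- sim$truth$spots[2, ]
  ctr <- round(c(tr$row, tr$col)) + 1L
  times <- frame_times(sim$movie)
  center <- sim$movie$frames[ctr[1], ctr[2], ]
  before <- center[times < 2 & times > 1]
  after <- center[times >= 2.2 & times < 3]
  expect_true(all(before > cfg$background + 0.5 * tr$amplitude))
  expect_true(all(abs(after - cfg$background) < 1e-6))
})

test_that("event validation rejects impossible schedules", {
  expect_error(simulation_config(event_schedule = data.frame(
    spot = 99L, time_s = 1, class = "full_fusion")), "nonexistent spot")
  expect_error(simulation_config(event_schedule = data.frame(
    spot = 1L, time_s = 1e5, class = "full_fusion")), "movie span")
  cfg <- simulation_config(event_schedule = data.frame(
    spot = 1L, time_s = 1, class = "response"))
  expect_error(simulate_ldcv_movie(cfg), "full_fusion")
})

test_that("SypHy construction arithmetic: plateau over baseline equals the pool ratio", {
  cfg <- simulation_config(n_spots = 4L, image_dim = c(64L, 64L),
                           n_frames = 300L, stim_onset = 12,
                           amplitude_jitter = 0, bleach_tau = 1e9,
                           background = 0, seed = 3L,
                           event_schedule = data.frame(
                             spot = 1L, time_s = 0.5, class = "response"))
  sim <- simulate_syphy_movie(cfg, surface_fraction = 0.1,
                              nh4_window = c(10, 15))
  times <- frame_times(sim$movie)
  tr <- sim$truth$synapses
  ctr <- round(c(tr$row[2], tr$col[2])) + 1L   # synapse without response
  trace <- sim$movie$frames[ctr[1], ctr[2], ]
  plateau <- max(trace[times >= 10 & times <= 15])
  baseline <- mean(trace[times < 0])
  expect_equal(plateau / baseline, 10, tolerance = 1e-6)
  expect_true(is.na(tr$response_time_s[2]))
  # responding synapse doubles at its programmed time
  ctr1 <- round(c(tr$row[1], tr$col[1])) + 1L
  t1 <- sim$movie$frames[ctr1[1], ctr1[2], ]
  pre <- mean(t1[times < 0])
  post <- mean(t1[times > 0.5 & times < 5])
  expect_equal(post / pre, 2, tolerance = 1e-6)
  expect_error(simulate_syphy_movie(cfg, surface_fraction = 2,
                                    nh4_window = c(10, 15)), "surface_fraction")
})

test_that("rendered vesicles obey the correlated Gaussian model", {
  # cor = 0, no noise: maximum is A at the center pixel
  p <- elliptical_gaussian(A = 200, x0 = 16, y0 = 16, x_width = 2,
                           y_width = 3, cor = 0)
  img <- render_sted_vesicles(list(p), c(33, 33))$image
  expect_equal(max(img), 200)
  expect_equal(which(img == max(img), arr.ind = TRUE)[1, ],
               c(row = 17, col = 17))

  # cor = 0.5: the iso-intensity quadratic form has a tilted principal axis
  p2 <- elliptical_gaussian(A = 1, x0 = 0, y0 = 0, x_width = 2, y_width = 3,
                            cor = 0.5)
  # quadratic form Q = [[1/xw^2, -cor/(xw yw)], [-cor/(xw yw), 1/yw^2]]
  Q <- matrix(c(1 / 4, -0.5 / 6, -0.5 / 6, 1 / 9), 2, 2)
  ev <- eigen(Q)$vectors[, 1]
  angle <- atan2(ev[2], ev[1])
  expect_gt(min(abs(angle), abs(abs(angle) - pi / 2)), 0.1)

  # empty parameter list renders an all-zero image
  expect_true(all(render_sted_vesicles(list(), c(16, 16))$image == 0))
  # out-of-range correlation is rejected
  pbad <- list(A = 1, x0 = 8, y0 = 8, x_width = 1, y_width = 1, cor = 1.2)
  expect_error(render_sted_vesicles(list(pbad), c(16, 16)), "cor")
})

test_that("Fura pair construction anchors at R_min and inverts exactly", {
  calib <- fura_calibration()
  zero <- simulate_fura_pair(matrix(0, 4, 4), calib)
  expect_equal(zero$f350 / zero$f380, matrix(calib$R_min, 4, 4),
               tolerance = 1e-12)

  # at [Ca] = Kd the inverted ratio satisfies (R - Rmin)/(Rmax - R) = 1/beta
  kd <- simulate_fura_pair(matrix(350, 2, 2), calib)
  R <- (kd$f350 / kd$f380)[1, 1]
  expect_equal((R - calib$R_min) / (calib$R_max - R), 1 / calib$beta,
               tolerance = 1e-12)

  # noiseless round trip through the analysis recovers truth to 1e-9 nM
  set.seed(8)
  ca <- matrix(runif(64, 0, 2000), 8, 8)
  pair <- simulate_fura_pair(ca, calib)
  out <- calcium_image(pair$f350, pair$f380, calib)
  expect_lt(max(abs(out$ca - ca)), 1e-9)
  expect_error(simulate_fura_pair(matrix(-1, 2, 2), calib), "non-negative")
})

test_that("coloc pairs carry their constructed Manders truth", {
  full <- simulate_coloc_pair(256L, 1, seed = 2L)
  expect_equal(full$truth$M1, 1)
  expect_equal(full$truth$M2, 1)
  none <- simulate_coloc_pair(256L, 0, seed = 2L)
  expect_equal(none$truth$M1, 0)
  expect_equal(none$truth$M2, 0)
  half <- simulate_coloc_pair(400L, 0.5, seed = 2L)
  expect_equal(half$truth$M1, 0.5)
  expect_equal(half$truth$M2, 0.5)
  expect_error(simulate_coloc_pair(256L, 1.4, seed = 1L), "overlap_fraction")
})

test_that("ground truth serializes losslessly to JSON", {
  cfg <- simulation_config(n_frames = 20L, stim_onset = 0.5,
                           event_schedule = data.frame(
    spot = 3L, time_s = 0.7, class = "kiss_and_run"))
  truth <- simulate_ldcv_movie(cfg)$truth
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$spots, truth$spots, tolerance = 1e-12)
  expect_equal(back$events$time_s, truth$events$time_s)
  expect_identical(back$events$class, truth$events$class)
  expect_equal(back$background, truth$background)
})

test_that("noise never alters the stored ground truth", {
  sch <- data.frame(spot = 1:2, time_s = c(1, 2),
                    class = c("full_fusion", "kiss_and_run"))
  clean <- simulate_ldcv_movie(simulation_config(
    seed = 4L, n_frames = 50L, stim_onset = 1, event_schedule = sch))
  noisy <- simulate_ldcv_movie(simulation_config(
    seed = 4L, n_frames = 50L, stim_onset = 1, noise_sd = 100,
    event_schedule = sch))
  expect_identical(clean$truth$spots, noisy$truth$spots)
  expect_identical(clean$truth$events, noisy$truth$events)
})
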