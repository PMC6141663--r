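# helper: bare trace object on a regular clock
make_trace <- function(values, dt = 0.1, t0 = -15) {
  structure(list(id = 1L, times = t0 + (seq_along(values) - 1L) * dt,
                 raw = values, normalized = NULL), class = "SynapseTrace")
}

test_that("synapse identification requires a plateau and immobility", {
  scen <- syphy_scenario(seed = 5L)
  sim <- simulate_syphy_movie(scen$config, surface_fraction = 0.1,
                              nh4_window = scen$nh4_window)
  mv <- subtract_background(sim$movie)
  rois <- identify_synapses(mv, scen$nh4_window)
  expect_equal(length(rois), 20L)
  tru <- sim$truth$synapses
  for (roi in rois) {
    ctr <- attr(roi, "centroid")
    d <- sqrt((tru$row - ctr[1])^2 + (tru$col - ctr[2])^2)
    expect_lt(min(d), 1)
    expect_gte(attr(roi, "plateau_ratio"), 2)
  }

  # punctum with no NH4 rise is rejected: constant spot, never changes
  h <- 48L
  flat <- vesiquant:::render_gaussian_spots(
    h, h, data.frame(row = 24, col = 24, amplitude = 800, sigma = 1.3))
  mv_flat <- movie_stack(array(rep(flat, 60), c(h, h, 60)), 0.16, 0.1,
                         stim_onset = 2)
  none <- identify_synapses(mv_flat, nh4_window = c(2, 3.8))
  expect_equal(length(none), 0L)

  # punctum drifting by 3 px between baseline and NH4 phases is rejected
  drift <- array(0, c(h, h, 60))
  for (t in 1:60) {
    row <- if (t <= 30) 20 else 23
    amp <- if (t <= 30) 300 else 3000   # NH4-like rise, but mobile
    drift[, , t] <- vesiquant:::render_gaussian_spots(
      h, h, data.frame(row = row, col = 24, amplitude = amp, sigma = 1.3))
  }
  mv_drift <- movie_stack(drift, 0.16, 0.1, stim_onset = 2)
  moved <- identify_synapses(mv_drift, nh4_window = c(1.1, 3.8))
  expect_equal(length(moved), 0L)
  cand <- attr(moved, "candidates")
  expect_true(any(cand$drift > 1))
})

test_that("NH4 normalization maps the trace onto pool fractions", {
  v <- c(rep(50, 150), rep(500, 30))
  tr <- make_trace(v, t0 = -15)
  ntr <- normalize_to_nh4(tr, nh4_window = c(0, 2.9))
  expect_equal(ntr$normalized[1], 0.1)
  expect_equal(max(ntr$normalized), 1)
  # invariance under expression-level rescaling
  ntr10 <- normalize_to_nh4(make_trace(10 * v, t0 = -15), c(0, 2.9))
  expect_equal(ntr10$normalized, ntr$normalized)
  # constant trace normalizes to identically 1
  ct <- normalize_to_nh4(make_trace(rep(42, 50), t0 = -2), c(0, 2))
  expect_true(all(ct$normalized == 1))
  # zero plateau is an error
  expect_error(normalize_to_nh4(make_trace(rep(0, 50), t0 = -2), c(0, 2)),
               "plateau")
})

test_that("response detection applies the 2xSD rule with a 2-frame sustain", {
  set.seed(42)
  base_sd <- 0.01
  noise <- rnorm(300, 0, base_sd)
  # step of 10 SD at t = 0.8 s
  tt0 <- -15
  step <- ifelse(tt0 + (0:299) * 0.1 >= 0.8, 10 * base_sd, 0)
  tr <- make_trace(0.1 + noise + step)
  t_hat <- detect_response_time(tr, baseline_window = c(-10, -1))
  expect_equal(as.numeric(t_hat), 0.8, tolerance = 1e-9)

  # flat noise trace never responds
  flat <- make_trace(0.1 + noise)
  expect_true(is.na(detect_response_time(flat, c(-10, -1))))

  # a single-frame spike fails the sustain rule
  spike <- 0.1 + noise
  spike[which.min(abs(tt0 + (0:299) * 0.1 - 2))] <- 0.1 + 10 * base_sd
  expect_true(is.na(detect_response_time(make_trace(spike), c(-10, -1))))

  # too-short baselines are refused
  expect_error(detect_response_time(make_trace(rnorm(20), t0 = 0),
                                    baseline_window = c(-10, -1)),
               "fewer than 5")
})

test_that("synchrony classification is an exhaustive partition", {
  expect_equal(classify_synchronization(0.8), "synchronized")
  expect_equal(classify_synchronization(-3), "pre_stimulus")
  expect_equal(classify_synchronization(5), "delayed")
  expect_equal(classify_synchronization(NA), "nonresponsive")
  # boundary: exactly at onset and exactly at the window edge
  expect_equal(classify_synchronization(0), "synchronized")
  expect_equal(classify_synchronization(1), "synchronized")
  expect_equal(classify_synchronization(1 + 1e-9), "delayed")
  # every input gets exactly one class
  set.seed(9)
  times <- c(NA, runif(200, -20, 20))
  cls <- classify_synchronization(times)
  expect_equal(length(cls), length(times))
  expect_true(all(cls %in% c("nonresponsive", "pre_stimulus",
                             "synchronized", "delayed")))
})

test_that("peak response measures the normalized rise over baseline", {
  v <- c(rep(50, 150), rep(100, 50), rep(500, 30))   # baseline, response, NH4
  tr <- normalize_to_nh4(make_trace(v), nh4_window = c(5, 7.9))
  pk <- peak_response(tr, stim_window = c(0, 5))
  expect_equal(pk, 0.1, tolerance = 1e-9)
  # flat trace gives ~0
  ft <- normalize_to_nh4(make_trace(c(rep(50, 200), rep(500, 30))),
                         c(5, 7.9))
  expect_equal(peak_response(ft, c(0, 5)), 0, tolerance = 1e-9)
  # monotone ramp peaks at the window end
  ramp <- c(rep(50, 150), seq(50, 150, length.out = 50), rep(500, 30))
  rtr <- normalize_to_nh4(make_trace(ramp), c(5, 7.9))
  expect_equal(peak_response(rtr, c(0, 5)),
               (ramp[200] - 50) / 500, tolerance = 1e-9)
  expect_error(peak_response(rtr, c(100, 101)), "empty")
})

test_that("synchrony summaries are fractions over responders", {
  cls <- c(rep("synchronized", 8), "pre_stimulus", "delayed")
  s <- summarize_synchrony(cls)
  expect_equal(unname(s$fractions), c(0.8, 0.1, 0.1))
  expect_equal(sum(s$fractions), 1)
  all_sync <- summarize_synchrony(rep("synchronized", 5))
  expect_equal(unname(all_sync$fractions), c(1, 0, 0))
  expect_error(summarize_synchrony(rep("nonresponsive", 3)), "undefined")
  expect_error(summarize_synchrony(character()), "empty")
  expect_error(summarize_synchrony(c("synchronized", "weird")), "unknown")
})

test_that("programmed SypHy scenes are classified perfectly", {
  scen <- syphy_scenario(seed = 7L)
  sim <- simulate_syphy_movie(scen$config, surface_fraction = 0.1,
                              nh4_window = scen$nh4_window)
  out <- analyze_syphy(subtract_background(sim$movie), scen$nh4_window)
  tru <- sim$truth$synapses
  expect_equal(nrow(out$table), nrow(tru))
  # match by position and compare class + response time
  rois <- identify_synapses(subtract_background(sim$movie), scen$nh4_window)
  for (i in seq_len(nrow(out$table))) {
    ctr <- attr(rois[[i]], "centroid")
    j <- which.min((tru$row - ctr[1])^2 + (tru$col - ctr[2])^2)
    expect_equal(out$table$class[i],
                 classify_synchronization(tru$response_time_s[j]))
    if (!is.na(tru$response_time_s[j]))
      expect_lte(abs(out$table$response_time_s[i] - tru$response_time_s[j]),
                 0.1 + 1e-9)
  }
  # expression-level invariance: a 10x brighter cell classifies identically
  bright <- sim$movie
  bright$frames <- bright$frames * 10
  out10 <- analyze_syphy(subtract_background(bright), scen$nh4_window)
  expect_equal(out10$table$class, out$table$class)
  expect_equal(out10$table$response_time_s, out$table$response_time_s)
  expect_equal(out10$table$peak_response, out$table$peak_response,
               tolerance = 1e-6)
})
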