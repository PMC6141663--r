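test_that("Manders coefficients match hand-computed cases", {
  a <- matrix(c(2, 0, 0, 2), 2, 2, byrow = TRUE)
  b <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)
  m <- manders_coefficients(a, b)
  expect_equal(m$M1, 0.5)
  expect_equal(m$M2, 0.5)

  set.seed(5)
  img <- matrix(runif(64, 0, 10), 8, 8)
  same <- manders_coefficients(img, img)
  expect_equal(same$M1, 1)
  expect_equal(same$M2, 1)

  da <- matrix(0, 4, 4); db <- matrix(0, 4, 4)
  da[1:2, ] <- 5; db[3:4, ] <- 5
  disj <- manders_coefficients(da, db)
  expect_equal(disj$M1, 0)
  expect_equal(disj$M2, 0)

  blank <- manders_coefficients(matrix(0, 3, 3), matrix(1, 3, 3))
  expect_true(blank$undefined)
  expect_true(is.na(blank$M1))
  expect_error(manders_coefficients(matrix(0, 2, 2), matrix(0, 3, 3)),
               "same shape")
})

test_that("Manders equals the exhaustive per-pixel oracle on random images", {
  for (seed in 1:100) {
    set.seed(seed)
    a <- matrix(sample(0:20, 64, replace = TRUE), 8, 8)
    b <- matrix(sample(0:20, 64, replace = TRUE), 8, 8)
    thrA <- sample(0:5, 1); thrB <- sample(0:5, 1)
    m <- manders_coefficients(a, b, thrA = thrA, thrB = thrB)
    o <- manders_bruteforce(a, b, thrA, thrB)
    expect_identical(m$M1, unname(o["M1"]))
    expect_identical(m$M2, unname(o["M2"]))
  }
})

test_that("measured Manders agrees with simulated ground truth", {
  for (f in c(0, 0.25, 0.5, 1)) {
    sim <- simulate_coloc_pair(1024L, f, seed = 11L)
    m <- manders_coefficients(sim$channelA, sim$channelB)
    expect_equal(m$M1, sim$truth$M1)
    expect_equal(m$M2, sim$truth$M2)
  }
})

test_that("synapse selection enforces the dual-channel 1,000-AU rule", {
  h <- 64L
  neurite <- roi_mask({m <- matrix(FALSE, h, h); m[28:36, ] <- TRUE; m})
  mk <- function(amps, cols) {
    img <- matrix(0, h, h)
    img[neurite$mask] <- 100   # neurite baseline
    img + vesiquant:::render_gaussian_spots(
      h, h, data.frame(row = 32, col = cols, amplitude = amps, sigma = 1.3))
  }
  # three puncta: both channels +1500; one channel only; both +500
  a <- mk(c(1500, 1500, 500), c(12, 32, 52))
  b <- mk(c(1500, 30, 500), c(12, 32, 52))
  cfg <- analysis_config(detect_threshold = 40)
  hits <- select_synapses(a, b, list(neurite), delta = 1000, config = cfg)
  expect_equal(nrow(hits), 1L)
  expect_lt(abs(hits$col - 12), 1)
  cand <- attr(hits, "candidates")
  expect_gte(nrow(cand), 2L)
})

test_that("line profiles reproduce constructed intensity structure", {
  # constant image gives a constant profile
  const <- matrix(3.5, 32, 32)
  path <- rbind(c(16, 4), c(16, 28))
  prof <- extract_line_profile(const, path, width = 3, pixel_size = 0.2)
  expect_true(all(abs(prof$intensity - 3.5) < 1e-12))
  expect_equal(diff(prof$position_um[1:2]), 0.2)

  # vertical path over a single bright row peaks only at the crossing
  img <- matrix(0, 32, 32)
  img[16, ] <- 10                     # bright row at row index 15 (0-based)
  vpath <- rbind(c(5, 16), c(27, 16))
  vp <- extract_line_profile(img, vpath, width = 1)
  expect_equal(sum(vp$intensity > 1e-9), 1L)
  expect_equal(vp$intensity[vp$position_um == 10], 10)

  # width 1 equals direct interpolation along the path
  set.seed(2)
  tex <- matrix(runif(32 * 32), 32, 32)
  p1 <- extract_line_profile(tex, path, width = 1)
  direct <- vapply(seq_along(p1$position_um), function(i)
    vesiquant:::bilinear_interp(tex, 16, 4 + p1$position_um[i]), numeric(1))
  expect_equal(p1$intensity, direct, tolerance = 1e-12)

  expect_error(extract_line_profile(tex, rbind(c(0, 0), c(200, 0))),
               "outside")
})

test_that("profile alignment centers the reference peak without amplitude loss", {
  # two copies of one delta-peak profile at offsets +2 and -2 samples
  base <- rep(0, 41); base[21] <- 100
  shift_by <- function(v, k) {
    out <- rep(0, length(v))
    src <- seq_along(v) - k
    ok <- src >= 1 & src <= length(v)
    out[ok] <- v[src[ok]]
    out
  }
  profs <- list(
    list(ref = shift_by(base, 2), other = shift_by(base, 2) / 2),
    list(ref = shift_by(base, -2), other = shift_by(base, -2) / 2))
  avg <- align_and_average_profiles(profs, reference = "ref")
  ctr <- which(avg$position_um == 0)
  expect_equal(avg$ref_mean[ctr], 100)
  expect_equal(sum(avg$ref_mean > 1e-9, na.rm = TRUE), 1L)
  expect_equal(avg$other_mean[ctr], 50)

  # averaging N copies of one profile returns that profile (idempotence)
  many <- replicate(5, list(ref = base, other = base * 0.3),
                    simplify = FALSE)
  avg5 <- align_and_average_profiles(many, "ref")
  expect_equal(avg5$ref_mean, base)
  # flat profiles stay flat wherever samples remain after alignment
  flat <- replicate(3, list(ref = rep(2, 11)), simplify = FALSE)
  avgf <- align_and_average_profiles(flat, "ref")
  expect_true(all(avgf$ref_mean[avgf$ref_n > 0] == 2))
  expect_error(align_and_average_profiles(profs, "missing"), "missing")
})

test_that("enrichment folds are ratios of center to flank intensity", {
  pos <- seq(-2, 2, by = 0.1)
  profile <- data.frame(position_um = pos,
                        intensity = ifelse(abs(pos) <= 0.5, 460, 100))
  expect_equal(enrichment_fold(profile), 4.6)
  # invariance under positive rescaling
  scaled <- transform(profile, intensity = intensity * 37.2)
  expect_equal(enrichment_fold(scaled), 4.6)
  flat <- data.frame(position_um = pos, intensity = 7)
  expect_equal(enrichment_fold(flat), 1.0)
  zero <- data.frame(position_um = pos,
                     intensity = ifelse(abs(pos) <= 0.5, 10, 0))
  expect_error(enrichment_fold(zero), "zero")
  expect_error(enrichment_fold(profile, center_halfwidth = 1,
                               flank_window = c(0.5, 1.5)), "overlap")
})

test_that("synapse density and soma distances follow the geometry", {
  expect_equal(synapse_density(matrix(0, 50, 2), 1000), 0.05)
  expect_equal(synapse_density(data.frame(row = numeric(),
                                          col = numeric()), 10), 0)
  expect_error(synapse_density(matrix(0, 5, 2), 0), "positive")

  square <- rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0))
  # point 5 px left of the square edge at 0.2 um/px
  expect_equal(nearest_soma_distance(c(5, -5), list(square), 0.2), 1.0)
  # on the boundary and inside: distance 0
  expect_equal(nearest_soma_distance(c(0, 5), list(square), 0.2), 0)
  expect_equal(nearest_soma_distance(c(5, 5), list(square), 0.2), 0)
  # nearest of several somata wins
  far <- rbind(c(100, 100), c(100, 110), c(110, 110), c(110, 100))
  expect_equal(nearest_soma_distance(c(5, -5), list(far, square), 0.2), 1.0)
  expect_error(nearest_soma_distance(c(1, 1), list(), 0.2), "outlines")
})
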