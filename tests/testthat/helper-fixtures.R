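# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (per-pixel loops, supersampling) and independent of the package's
# implementation paths.

# rectangular ROI covering a whole H x W image (pixel centers 0..h-1)
full_frame_roi <- function(h, w) {
  roi_polygon(rbind(c(-0.5, -0.5), c(-0.5, w - 0.5),
                    c(h - 0.5, w - 0.5), c(h - 0.5, -0.5)))
}

# brute-force Manders coefficients by explicit per-pixel loops
manders_bruteforce <- function(a, b, thrA = 0, thrB = 0) {
  numA <- 0; denA <- 0; numB <- 0; denB <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (a[i, j] > thrA) denA <- denA + a[i, j]
      if (b[i, j] > thrB) { denB <- denB + b[i, j]; numA <- numA + a[i, j] }
      if (a[i, j] > thrA) numB <- numB + b[i, j]
    }
  }
  c(M1 = if (denA > 0) numA / denA else NA_real_,
    M2 = if (denB > 0) numB / denB else NA_real_)
}

# supersampled rasterization area of a polygon (px^2): fraction of each
# pixel covered, estimated on a k x k subgrid of the pixel
polygon_raster_area <- function(vertices, h, w, k = 8L) {
  bnd <- rbind(vertices, vertices[1L, ])
  off <- (seq_len(k) - 0.5) / k - 0.5
  total <- 0
  for (r in 0:(h - 1L)) {
    pts <- cbind(rep(r + off, times = w * k),
                 rep(rep(0:(w - 1L), each = k) +
                       rep(off, times = w), each = k))
    total <- total + sum(mgcv::in.out(bnd, pts)) / k^2
  }
  total
}

# default whole-image footprint used in LDCV tests
ldcv_footprint <- function(dim = c(64L, 64L)) full_frame_roi(dim[1L], dim[2L])

# standard three-event schedule (two full fusions, one kiss-and-run),
# placed in the stimulus phase of the default 200-frame movie
three_event_schedule <- function() {
  data.frame(spot = 1:3, time_s = c(2, 4, 6),
             class = c("full_fusion", "kiss_and_run", "full_fusion"))
}

# match detected events against truth; returns counts for recall/precision
match_events <- function(found, truth, max_dist = 3, max_dt = 0.35,
                         check_class = TRUE) {
  matched <- logical(nrow(truth))
  fp <- 0L
  for (k in seq_len(nrow(found))) {
    d <- sqrt((truth$row - found$row[k])^2 + (truth$col - found$col[k])^2)
    ok <- d < max_dist & abs(truth$time_s - found$time_s[k]) <= max_dt &
      !matched
    if (check_class) ok <- ok & truth$class == found$class[k]
    hit <- which(ok)
    if (length(hit)) matched[hit[1L]] <- TRUE else fp <- fp + 1L
  }
  list(tp = sum(matched), fn = sum(!matched), fp = fp)
}

# SypHy scenario with programmed response times spanning all four classes
syphy_scenario <- function(seed = 7L, noise_sd = 0) {
  rt <- c(rep(NA, 4), rep(-0.5, 3),
          c(0.3, 0.5, 0.8, 0.2, 0.6, 0.9, 0.4), rep(c(3, 5, 8), 2))
  resp <- which(!is.na(rt))
  cfg <- simulation_config(
    n_spots = 20L, image_dim = c(96L, 96L), n_frames = 450L,
    stim_onset = 15, spot_amplitude = 2000, background = 100,
    noise_sd = noise_sd, seed = seed,
    event_schedule = data.frame(spot = resp, time_s = rt[resp],
                                class = "response"))
  list(config = cfg, response_times = rt, nh4_window = c(20, 25))
}
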