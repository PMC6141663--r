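# Ground-truthed synthetic scenes: TIRF movies of secretory vesicles with
# scheduled fusion events, SypHy movies with programmed responses and an
# NH4Cl plateau, super-resolution vesicle renders, Fura-2 ratio pairs and
# two-channel colocalization fixtures. Every generator records complete
# truth so the matching analysis stage can be validated exactly.

#' Simulation configuration
#'
#' Conditions for the movie generators. The defaults emulate the TIRF
#' recording conditions the analyses assume: immobile diffraction-limited
#' puncta imaged at 10 Hz with 160 nm pixels, a 10 Hz pre-stimulus phase
#' followed by a 100 Hz stimulus phase, mild mono-exponential bleaching and
#' additive Gaussian read noise (optionally Poisson shot noise).
#'
#' @param n_spots number of rendered puncta.
#' @param image_dim image size `c(H, W)` in pixels.
#' @param n_frames number of frames.
#' @param frame_interval seconds per frame (0.1 = 10 Hz).
#' @param pixel_size micrometers per pixel.
#' @param stim_onset stimulus onset on the movie clock (s); the pre-stimulus
#'   phase runs from the movie start to this time.
#' @param psf_sigma isotropic point-spread-function sigma in pixels.
#' @param spot_amplitude peak spot amplitude (AU) above background.
#' @param amplitude_jitter relative spot-to-spot amplitude spread (uniform
#'   within `1 +/- amplitude_jitter`).
#' @param background constant background level (AU).
#' @param noise_sd Gaussian read-noise standard deviation (AU); the
#'   signal-to-noise ratio is `spot_amplitude / noise_sd`.
#' @param poisson_noise add Poisson shot noise on top of the rendered
#'   intensities?
#' @param bleach_tau mono-exponential bleaching time constant (s) applied to
#'   all spot amplitudes.
#' @param kiss_amp_factor,kiss_width_factor,kiss_duration rendering of a
#'   kiss-and-run event: the spot brightens by `kiss_amp_factor` and widens
#'   by `kiss_width_factor` (the released cargo cloud) for `kiss_duration`
#'   seconds, then disappears.
#' @param protocol data frame of stimulation phases with columns `label`,
#'   `start_s`, `end_s`, `rate_hz` (times relative to stimulus onset).
#'   `NULL` builds the default two-phase protocol from `stim_onset` and the
#'   movie span.
#' @param event_schedule data frame of scheduled events with columns `spot`,
#'   `time_s` (relative to stimulus onset) and `class` (`"full_fusion"`,
#'   `"kiss_and_run"`, or `"response"` for SypHy movies). At most one event
#'   per spot.
#' @param min_separation minimum pairwise spot distance in pixels; default
#'   `8 * psf_sigma`, so the measurement apertures of neighboring spots do
#'   not overlap.
#' @param seed integer random seed; a fixed seed makes every generator
#'   bit-reproducible.
#' @return an object of class `SimulationConfig`.
#' @export
simulation_config <- function(n_spots = 10L,
                              image_dim = c(64L, 64L),
                              n_frames = 200L,
                              frame_interval = 0.1,
                              pixel_size = 0.16,
                              stim_onset = 10,
                              psf_sigma = 1.3,
                              spot_amplitude = 1000,
                              amplitude_jitter = 0.1,
                              background = 100,
                              noise_sd = 0,
                              poisson_noise = FALSE,
                              bleach_tau = 300,
                              kiss_amp_factor = 2,
                              kiss_width_factor = 1.5,
                              kiss_duration = 0.3,
                              protocol = NULL,
                              event_schedule = NULL,
                              min_separation = NULL,
                              seed = 1L) {
  if (spot_amplitude <= 0) stop("'spot_amplitude' must be positive")
  if (psf_sigma <= 0) stop("'psf_sigma' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (bleach_tau <= 0) stop("'bleach_tau' must be positive")
  span <- c(-stim_onset, (n_frames - 1L) * frame_interval - stim_onset)
  if (is.null(protocol))
    protocol <- data.frame(
      label = c("pre_stimulus", "stimulus"),
      start_s = c(span[1L], 0),
      end_s = c(0, span[2L]),
      rate_hz = c(10, 100))
  if (is.null(event_schedule))
    event_schedule <- data.frame(spot = integer(), time_s = numeric(),
                                 class = character())
  if (nrow(event_schedule)) {
    if (anyDuplicated(event_schedule$spot))
      stop("at most one scheduled event per spot")
    if (any(event_schedule$spot < 1L | event_schedule$spot > n_spots))
      stop("event scheduled for a nonexistent spot")
    if (any(event_schedule$time_s < span[1L] |
              event_schedule$time_s > span[2L]))
      stop("event time outside the movie span")
  }
  structure(list(n_spots = as.integer(n_spots),
                 image_dim = as.integer(image_dim),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, pixel_size = pixel_size,
                 stim_onset = stim_onset, psf_sigma = psf_sigma,
                 spot_amplitude = spot_amplitude,
                 amplitude_jitter = amplitude_jitter,
                 background = background, noise_sd = noise_sd,
                 poisson_noise = poisson_noise, bleach_tau = bleach_tau,
                 kiss_amp_factor = kiss_amp_factor,
                 kiss_width_factor = kiss_width_factor,
                 kiss_duration = kiss_duration, protocol = protocol,
                 event_schedule = event_schedule,
                 min_separation = if (is.null(min_separation)) 8 * psf_sigma
                                  else min_separation,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# Draw spot positions away from the borders, with a minimum pairwise
# separation (docked vesicles and synapses are sparse at the footprint),
# and jittered amplitudes. Must be called inside with_seed().
.draw_spots <- function(config) {
  h <- config$image_dim[1L]; w <- config$image_dim[2L]
  margin <- 4 * config$psf_sigma
  if (2 * margin >= min(h, w) - 1)
    stop("image too small for the requested PSF margin")
  n <- config$n_spots
  minsep2 <- config$min_separation^2
  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L
  for (attempt in seq_len(5000L)) {
    r <- runif(1L, margin, h - 1 - margin)
    c <- runif(1L, margin, w - 1 - margin)
    if (placed == 0L ||
          all((rows[seq_len(placed)] - r)^2 +
                (cols[seq_len(placed)] - c)^2 >= minsep2)) {
      placed <- placed + 1L
      rows[placed] <- r; cols[placed] <- c
      if (placed == n) break
    }
  }
  if (placed < n)
    stop("could not place ", n, " spots at the requested separation")
  data.frame(
    id = seq_len(n),
    row = rows, col = cols,
    amplitude = config$spot_amplitude *
      runif(n, 1 - config$amplitude_jitter, 1 + config$amplitude_jitter),
    sigma = config$psf_sigma)
}

.protocol_phase <- function(protocol, time_s) {
  hit <- which(time_s >= protocol$start_s & time_s < protocol$end_s)
  if (!length(hit)) hit <- which(time_s == protocol$end_s)
  if (!length(hit)) NA_character_ else protocol$label[hit[1L]]
}

.add_noise <- function(frames, config) {
  if (config$poisson_noise) {
    frames[] <- rpois(length(frames), pmax(frames, 0))
  }
  if (config$noise_sd > 0) {
    frames <- frames + rnorm(length(frames), 0, config$noise_sd)
  }
  pmax(frames, 0)
}

#' Simulate a TIRF movie of secretory vesicles with scheduled fusion events
#'
#' Renders immobile Gaussian puncta on a constant background. A scheduled
#' `full_fusion` event removes its spot at the event time; a `kiss_and_run`
#' event transiently brightens and widens the spot (the released cargo
#' cloud) for `kiss_duration` seconds and then removes it. Amplitudes bleach
#' mono-exponentially; noise is added last and never alters the recorded
#' truth.
#'
#' @param config a [simulation_config()] whose `event_schedule` uses classes
#'   `"full_fusion"` / `"kiss_and_run"`.
#' @return a list with elements `movie` (a `MovieStack`) and `truth` (a
#'   `SceneGroundTruth` list: `spots`, `events` with stimulation phase, and
#'   the generating conditions).
#' @export
simulate_ldcv_movie <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  ev <- config$event_schedule
  if (nrow(ev) && !all(ev$class %in% c("full_fusion", "kiss_and_run")))
    stop("LDCV event classes must be 'full_fusion' or 'kiss_and_run'")
  with_seed(config$seed, {
    spots <- .draw_spots(config)
    h <- config$image_dim[1L]; w <- config$image_dim[2L]
    frames <- array(config$background,
                    dim = c(h, w, config$n_frames))
    etime <- rep(Inf, config$n_spots)   # event start, stimulus-relative
    eclass <- rep(NA_character_, config$n_spots)
    if (nrow(ev)) { etime[ev$spot] <- ev$time_s; eclass[ev$spot] <- ev$class }
    for (t in seq_len(config$n_frames)) {
      clock <- (t - 1L) * config$frame_interval
      trel <- clock - config$stim_onset
      bleach <- exp(-clock / config$bleach_tau)
      live <- spots
      live$amplitude <- live$amplitude * bleach
      gone <- (eclass == "full_fusion" & trel >= etime) |
        (eclass == "kiss_and_run" & trel >= etime + config$kiss_duration)
      kiss <- eclass == "kiss_and_run" & trel >= etime &
        trel < etime + config$kiss_duration
      kiss[is.na(kiss)] <- FALSE; gone[is.na(gone)] <- FALSE
      live$amplitude[kiss] <- live$amplitude[kiss] * config$kiss_amp_factor
      live$sigma[kiss] <- live$sigma[kiss] * config$kiss_width_factor
      live <- live[!gone, , drop = FALSE]
      frames[, , t] <- frames[, , t] + render_gaussian_spots(h, w, live)
    }
    frames <- .add_noise(frames, config)
    events <- if (nrow(ev)) {
      data.frame(spot = ev$spot, time_s = ev$time_s, class = ev$class,
                 row = spots$row[ev$spot], col = spots$col[ev$spot],
                 phase = vapply(ev$time_s,
                                function(tt) .protocol_phase(config$protocol, tt),
                                character(1L)))
    } else {
      data.frame(spot = integer(), time_s = numeric(), class = character(),
                 row = numeric(), col = numeric(), phase = character())
    }
    list(movie = movie_stack(frames, config$pixel_size,
                             config$frame_interval, config$stim_onset,
                             "NPY-Venus (synthetic)"),
         truth = structure(list(type = "ldcv", spots = spots,
                                events = events, background = config$background,
                                protocol = config$protocol,
                                seed = config$seed),
                           class = "SceneGroundTruth"))
  })
}

#' Simulate a SypHy movie with programmed synapse responses
#'
#' Each synapse punctum carries a total (NH4Cl-revealed) pool; at rest only
#' `surface_fraction` of it is fluorescent. A programmed response at its
#' scheduled time (event class `"response"` in the configuration) adds
#' `response_delta` of the pool; inside `nh4_window` the full pool is
#' visible as a plateau.
#'
#' @param config a [simulation_config()]; entries of `event_schedule` with
#'   class `"response"` set per-synapse response times (stimulus-relative
#'   seconds); synapses without an entry never respond.
#' @param surface_fraction resting surface fraction of the pool, in `[0, 1]`.
#' @param nh4_window `(start, end)` of the NH4Cl application, in
#'   stimulus-relative seconds; must lie after stimulus onset.
#' @param response_delta pool fraction added by a response; default
#'   `surface_fraction` (a doubling of the resting signal).
#' @return a list with `movie` (a `MovieStack`) and `truth` (synapse table
#'   with pools and response times, the NH4 window and conditions).
#' @export
simulate_syphy_movie <- function(config, surface_fraction = 0.1,
                                 nh4_window, response_delta = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (surface_fraction < 0 || surface_fraction > 1)
    stop("'surface_fraction' must lie in [0, 1]")
  span_end <- (config$n_frames - 1L) * config$frame_interval -
    config$stim_onset
  if (length(nh4_window) != 2L || diff(nh4_window) <= 0 ||
      nh4_window[1L] < 0 || nh4_window[2L] > span_end + 1e-9)
    stop("'nh4_window' must be an increasing window after stimulus onset, ",
         "inside the movie span")
  if (is.null(response_delta)) response_delta <- surface_fraction
  ev <- config$event_schedule
  if (nrow(ev) && !all(ev$class == "response"))
    stop("SypHy event classes must all be 'response'")
  with_seed(config$seed, {
    spots <- .draw_spots(config)   # amplitude column = total pool
    rt <- rep(NA_real_, config$n_spots)
    if (nrow(ev)) rt[ev$spot] <- ev$time_s
    h <- config$image_dim[1L]; w <- config$image_dim[2L]
    frames <- array(config$background, dim = c(h, w, config$n_frames))
    for (t in seq_len(config$n_frames)) {
      clock <- (t - 1L) * config$frame_interval
      trel <- clock - config$stim_onset
      live <- spots
      frac <- rep(surface_fraction, config$n_spots)
      responded <- !is.na(rt) & trel >= rt
      frac[responded] <- surface_fraction + response_delta
      if (trel >= nh4_window[1L] && trel <= nh4_window[2L]) frac[] <- 1
      live$amplitude <- spots$amplitude * pmin(frac, 1) *
        exp(-clock / config$bleach_tau)
      frames[, , t] <- frames[, , t] + render_gaussian_spots(h, w, live)
    }
    frames <- .add_noise(frames, config)
    synapses <- data.frame(id = spots$id, row = spots$row, col = spots$col,
                           pool = spots$amplitude,
                           surface_fraction = surface_fraction,
                           response_time_s = rt)
    list(movie = movie_stack(frames, config$pixel_size,
                             config$frame_interval, config$stim_onset,
                             "SypHy (synthetic)"),
         truth = structure(list(type = "syphy", synapses = synapses,
                                nh4_window = nh4_window,
                                response_delta = response_delta,
                                background = config$background,
                                seed = config$seed),
                           class = "SceneGroundTruth"))
  })
}

#' Render super-resolution vesicle images from known parameters
#'
#' Sums the correlated elliptical Gaussian surface of every parameter set
#' onto one image and optionally adds Gaussian noise. The exact parameters
#' are stored as truth for recovery tests.
#'
#' @param params list of [elliptical_gaussian()] parameter sets; each
#'   vesicle's `3 * max(x_width, y_width)` footprint must lie inside the
#'   image.
#' @param image_dim image size `c(H, W)` in pixels.
#' @param noise_sd Gaussian noise standard deviation (AU).
#' @param pixel_size micrometers per pixel (default 0.025, i.e. 25 nm).
#' @param seed random seed for the noise.
#' @return a list with `image` (H x W matrix) and `truth` (the parameter
#'   list and conditions).
#' @export
render_sted_vesicles <- function(params, image_dim = c(32L, 32L),
                                 noise_sd = 0, pixel_size = 0.025,
                                 seed = 1L) {
  h <- image_dim[1L]; w <- image_dim[2L]
  img <- matrix(0, h, w)
  for (p in params) {
    if (abs(p$cor) >= 1) stop("'cor' outside (-1, 1)")
    foot <- 3 * max(p$x_width, p$y_width)
    if (p$x0 - foot < 0 || p$x0 + foot > h - 1 ||
        p$y0 - foot < 0 || p$y0 + foot > w - 1)
      stop("vesicle footprint extends outside the image")
    img <- img + render_gaussian2d(p, h, w)
  }
  if (noise_sd > 0)
    img <- with_seed(seed, img + matrix(rnorm(h * w, 0, noise_sd), h, w))
  list(image = img,
       truth = structure(list(type = "sted", params = params,
                              pixel_size = pixel_size, noise_sd = noise_sd,
                              seed = seed),
                         class = "SceneGroundTruth"))
}

#' Simulate a Fura-2 350/380 image pair with known calcium
#'
#' Inverts the ratiometric calibration so that [ratio_image()] followed by
#' [calcium_from_ratio()] recovers `true_ca` exactly in the noiseless case:
#' `R = (Ca * R_max + K_d * beta * R_min) / (Ca + K_d * beta)`, `f380` is a
#' flat field at `f380_level`, and `f350 = R * f380`.
#'
#' @param true_ca matrix of true calcium concentrations (nM), finite and
#'   non-negative.
#' @param calib a [fura_calibration()].
#' @param f380_level fluorescence level (AU) of the 380 nm image.
#' @param bg350,bg380 additive backgrounds (AU) of the two images.
#' @param noise_sd Gaussian noise standard deviation (AU).
#' @param seed random seed for the noise.
#' @return a list with `f350`, `f380` and `truth` (the calcium map, the
#'   implied ratio image and the generating conditions).
#' @export
simulate_fura_pair <- function(true_ca, calib, f380_level = 1000,
                               bg350 = 0, bg380 = 0, noise_sd = 0,
                               seed = 1L) {
  true_ca <- as.matrix(true_ca)
  if (!all(is.finite(true_ca)) || any(true_ca < 0))
    stop("'true_ca' must be finite and non-negative")
  kb <- calib$K_d * calib$beta
  R <- (true_ca * calib$R_max + kb * calib$R_min) / (true_ca + kb)
  if (any(R >= calib$R_max))
    stop("'true_ca' implies a ratio at or above R_max")
  f380 <- matrix(f380_level, nrow(true_ca), ncol(true_ca)) + bg380
  f350 <- R * f380_level + bg350
  if (noise_sd > 0) {
    with_seed(seed, {
      f350 <- f350 + matrix(rnorm(length(f350), 0, noise_sd), nrow(f350))
      f380 <- f380 + matrix(rnorm(length(f380), 0, noise_sd), nrow(f380))
    })
  }
  list(f350 = f350, f380 = f380,
       truth = structure(list(type = "fura", true_ca = true_ca, ratio = R,
                              f380_level = f380_level, bg350 = bg350,
                              bg380 = bg380, noise_sd = noise_sd,
                              calibration = unclass(calib)),
                         class = "SceneGroundTruth"))
}

#' Simulate a two-channel pair with controlled co-occurrence
#'
#' Builds two binary-support images over a common pixel domain whose true
#' Manders coefficients follow from the construction: each channel occupies
#' `support_fraction` of the domain and the two supports share
#' `overlap_fraction` of their pixels.
#'
#' @param n_pixels number of pixels in the sampling domain.
#' @param overlap_fraction fraction of each channel's support shared with
#'   the other, in `[0, 1]`.
#' @param seed random seed.
#' @param support_fraction fraction of the domain covered by each channel.
#' @param amplitude intensity (AU) of support pixels.
#' @return a list with `channelA`, `channelB` (square matrices) and `truth`
#'   (supports and the constructed `M1`, `M2`).
#' @export
simulate_coloc_pair <- function(n_pixels = 4096L, overlap_fraction,
                                seed = 1L, support_fraction = 0.25,
                                amplitude = 1000) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("'overlap_fraction' must lie in [0, 1]")
  side <- ceiling(sqrt(n_pixels))
  k <- max(1L, round(support_fraction * n_pixels))
  m <- round(overlap_fraction * k)
  if (2L * k - m > n_pixels)
    stop("supports do not fit the domain; lower 'support_fraction'")
  with_seed(seed, {
    pick <- sample.int(n_pixels, 2L * k - m)
    idxA <- pick[seq_len(k)]
    idxB <- if (m == k) idxA
            else c(pick[seq_len(m)], pick[(k + 1L):(2L * k - m)])
    a <- matrix(0, side, side); b <- matrix(0, side, side)
    a[idxA] <- amplitude; b[idxB] <- amplitude
    # truth by construction: intensity-weighted co-occurrence of the supports
    m1 <- sum(a[b > 0]) / sum(a)
    m2 <- sum(b[a > 0]) / sum(b)
    list(channelA = a, channelB = b,
         truth = structure(list(type = "coloc", M1 = m1, M2 = m2,
                                n_overlap = m, n_support = k,
                                n_pixels = n_pixels, seed = seed),
                           class = "SceneGroundTruth"))
  })
}

#' Serialize scene ground truth to JSON
#'
#' @param truth a `SceneGroundTruth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  x$schema <- "vesiquant-ground-truth/1"
  x$coordinate_convention <- "0-based, pixel-centered, (row, col)"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Read scene ground truth back from JSON
#'
#' @param path a file written by [write_ground_truth()].
#' @return a `SceneGroundTruth` list.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$schema <- NULL
  x$coordinate_convention <- NULL
  for (nm in intersect(names(x), c("spots", "events", "synapses")))
    x[[nm]] <- as.data.frame(x[[nm]])
  structure(x, class = "SceneGroundTruth")
}
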