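# Large dense-core vesicle exocytosis at the TIRF footprint: punctum
# detection, fixed-position trace extraction, fusion-event classification
# (full fusion vs kiss-and-run) and the normalized secretion statistics.

#' Detect diffraction-limited puncta in a single frame
#'
#' Band-pass detection: the frame is filtered with a difference of Gaussians
#' at `psf_sigma` and `1.6 * psf_sigma`; local maxima of the response above
#' `threshold` become candidate spots, refined to sub-pixel position by 3x3
#' quadratic interpolation. Candidates closer than `2 * psf_sigma` are
#' merged, the brighter peak winning.
#'
#' @param frame background-subtracted image matrix.
#' @param psf_sigma point-spread-function sigma in pixels.
#' @param threshold minimal band-pass response (AU). For a Gaussian spot the
#'   band-pass peak is about 0.22 of the spot amplitude, so a threshold of
#'   `0.1 * amplitude` is a conservative default.
#' @return data frame with 0-based columns `row`, `col` and the band-pass
#'   `response`, ordered by decreasing response.
#' @export
detect_spots <- function(frame, psf_sigma, threshold) {
  if (!is.matrix(frame)) stop("'frame' must be a matrix")
  if (!is.numeric(psf_sigma) || psf_sigma <= 0)
    stop("'psf_sigma' must be positive")
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be positive")
  empty <- data.frame(row = numeric(), col = numeric(), response = numeric())
  h <- nrow(frame); w <- ncol(frame)
  if (h < 3L || w < 3L) return(empty)
  dog <- EBImage::gblur(frame, sigma = psf_sigma) -
    EBImage::gblur(frame, sigma = 1.6 * psf_sigma)
  # strict local maxima over the 8-neighborhood, away from the 1-px border
  core <- dog[2:(h - 1L), 2:(w - 1L)]
  is_max <- core > dog[1:(h - 2L), 2:(w - 1L)] &
    core > dog[3:h, 2:(w - 1L)] &
    core > dog[2:(h - 1L), 1:(w - 2L)] &
    core > dog[2:(h - 1L), 3:w] &
    core > dog[1:(h - 2L), 1:(w - 2L)] &
    core > dog[1:(h - 2L), 3:w] &
    core > dog[3:h, 1:(w - 2L)] &
    core > dog[3:h, 3:w] &
    core >= threshold
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  r <- idx[, 1L] + 1L; c <- idx[, 2L] + 1L   # 1-based in the full frame
  # 3x3 quadratic sub-pixel refinement per axis
  refine <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    off <- ifelse(den < 0, 0.5 * (vm - vp) / den, 0)
    pmax(pmin(off, 0.5), -0.5)
  }
  dr <- refine(dog[cbind(r - 1L, c)], dog[cbind(r, c)], dog[cbind(r + 1L, c)])
  dc <- refine(dog[cbind(r, c - 1L)], dog[cbind(r, c)], dog[cbind(r, c + 1L)])
  out <- data.frame(row = r - 1L + dr, col = c - 1L + dc,
                    response = dog[cbind(r, c)])
  out <- out[order(-out$response), , drop = FALSE]
  # minimum pairwise separation: greedy, brighter peak wins
  keep <- logical(nrow(out))
  minsep2 <- (2 * psf_sigma)^2
  for (i in seq_len(nrow(out))) {
    ok <- TRUE
    for (j in which(keep)) {
      if ((out$row[i] - out$row[j])^2 + (out$col[i] - out$col[j])^2 <
            minsep2) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Track immobile vesicle spots at the cell footprint
#'
#' Spots are detected once on the temporal-median image (robust to isolated
#' fusion events) and restricted to the footprint ROI; each spot's intensity
#' trace is then read out at its fixed position as the mean over a disk of
#' `config$trace_radius` pixels, together with a per-frame moment width used
#' by the event classifier. The movie is assumed background-subtracted.
#'
#' @param movie a background-subtracted `MovieStack`.
#' @param footprint `RegionOfInterest` delimiting the cell footprint.
#' @param config an [analysis_config()].
#' @return list of `VesicleSpot` objects: `id`, `position` (0-based
#'   (row, col)), `times` (stimulus-relative s), `trace` (AU) and
#'   `width` (px).
#' @export
track_footprint_spots <- function(movie, footprint, config = analysis_config()) {
  stopifnot(inherits(movie, "MovieStack"))
  mask <- roi_rasterize(footprint, dim(movie$frames)[1:2])
  if (!any(mask)) stop("footprint ROI covers no pixels")
  med <- apply(movie$frames, c(1L, 2L), median)
  spots <- detect_spots(med, config$psf_sigma, config$detect_threshold)
  if (nrow(spots)) {
    inside <- mask[cbind(round(spots$row) + 1L, round(spots$col) + 1L)]
    spots <- spots[inside, , drop = FALSE]
  }
  times <- frame_times(movie)
  d <- dim(movie$frames)
  r1 <- 2 * config$psf_sigma; r2 <- 4 * config$psf_sigma
  lapply(seq_len(nrow(spots)), function(i) {
    ctr <- c(spots$row[i], spots$col[i])
    n1 <- nrow(disk_pixels(ctr, r1, d[1:2]))
    n2 <- nrow(disk_pixels(ctr, r2, d[1:2]))
    # local background from an annulus just outside the outer aperture;
    # this also absorbs the positive noise floor that pixel-level clamping
    # leaves behind on noisy frames
    local_bg <- annulus_trace(movie$frames, ctr, r2, r2 + 2)
    core <- (disk_trace(movie$frames, ctr, r1) - local_bg) * n1
    outer <- (disk_trace(movie$frames, ctr, r2) - local_bg) * n2
    structure(list(id = i, position = ctr, times = times,
                   trace = disk_trace(movie$frames, ctr, config$trace_radius) -
                     local_bg,
                   width = aperture_width(core, outer, r1, r2)),
              class = "VesicleSpot")
  })
}

# Classification of a single spot trace; returns NULL or a one-row event.
.classify_one_spot <- function(spot, config, dt) {
  x <- spot$trace
  n <- length(x)
  if (n < 5L) return(NULL)
  win <- max(3L, round(1 / dt))
  M <- running_median(x, win)
  # reference level of the intact spot; once the trace has collapsed well
  # below it (the spot is gone), later excursions -- e.g. light leaking in
  # from a neighboring event -- are not credited to this spot
  B0 <- median(x[seq_len(min(length(x), win))])
  alive <- function(m0) m0 >= 0.3 * B0
  k_drop <- max(1L, floor(config$full_fusion_max_duration / dt))
  k_hold <- max(1L, ceiling(config$full_fusion_nonrecovery / dt))
  k_kiss <- max(1L, floor(config$kiss_max_duration / dt))

  ev <- function(i, cls) data.frame(
    spot = spot$id, time_s = spot$times[i], class = cls,
    row = spot$position[1L], col = spot$position[2L])

  # kiss-and-run first: transient rise + cloud, then loss. The subsequent
  # removal would otherwise satisfy the full-fusion drop as well.
  base_width <- NA_real_
  for (i in 2:n) {
    m0 <- M[i]
    if (m0 <= 0 || !alive(m0)) next
    if (x[i] >= config$kiss_rise_factor * m0 &&
          x[i - 1L] < config$kiss_rise_factor * M[i - 1L]) {
      run <- i
      while (run < n && x[run + 1L] >= config$kiss_rise_factor * m0)
        run <- run + 1L
      len <- run - i + 1L
      if (len > k_kiss) next
      after <- (run + 1L):min(n, run + k_hold)
      if (run >= n || !all(x[after] <= config$full_fusion_high * m0)) next
      base_width <- median(spot$width[1:(i - 1L)], na.rm = TRUE)
      exc_width <- mean(spot$width[i:run], na.rm = TRUE)
      if (is.finite(base_width) && is.finite(exc_width) &&
            exc_width >= config$kiss_width_factor * base_width)
        return(ev(i, "kiss_and_run"))
    }
  }
  # full fusion: fall from >= high to <= low of the pre-event running median
  # within the allowed duration, without recovery
  for (i in 2:n) {
    m0 <- M[i]
    if (m0 <= 0 || !alive(m0)) next
    if (x[i] < config$full_fusion_high * m0 &&
          x[i - 1L] >= config$full_fusion_high * M[i - 1L]) {
      lowby <- min(n, i + k_drop)
      j <- which(x[i:lowby] <= config$full_fusion_low * m0)
      if (!length(j)) next
      j <- i + j[1L] - 1L
      hold <- j:min(n, j + k_hold)
      if (all(x[hold] < config$full_fusion_high * m0))
        return(ev(i, "full_fusion"))
    }
  }
  NULL
}

#' Classify fusion events on tracked vesicle spots
#'
#' A spot trace yields a *full fusion* when it falls from at least
#' `full_fusion_high` (50%) to at most `full_fusion_low` (10%) of its
#' pre-event running median within `full_fusion_max_duration` (200 ms) and
#' does not recover for `full_fusion_nonrecovery` (1 s). It yields a
#' *kiss-and-run* when it transiently rises by `kiss_rise_factor` (1.5x) for
#' at most `kiss_max_duration` (0.5 s) with a concurrent spot-width increase
#' of `kiss_width_factor` (1.3x, the released cargo cloud) and subsequent
#' loss of the spot. The event time is the first frame of the excursion; at
#' most one event is reported per spot.
#'
#' @param spots list of `VesicleSpot` from [track_footprint_spots()].
#' @param config an [analysis_config()].
#' @param frame_interval seconds per frame; taken from the spot time stamps
#'   when omitted.
#' @return data frame of events: `spot`, `time_s` (stimulus-relative),
#'   `class`, `row`, `col`.
#' @export
classify_fusion_events <- function(spots, config = analysis_config(),
                                   frame_interval = NULL) {
  if (is.null(frame_interval)) {
    if (!length(spots) || length(spots[[1L]]$times) < 2L)
      stop("'frame_interval' is required when spots carry no time stamps")
    frame_interval <- diff(spots[[1L]]$times[1:2])
  }
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("'frame_interval' must be positive")
  out <- lapply(spots, .classify_one_spot, config = config,
                dt = frame_interval)
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(spot = integer(), time_s = numeric(),
                      class = character(), row = numeric(), col = numeric())
  rownames(out) <- NULL
  out
}

#' Cumulative exocytosis curve normalized to the cohort footprint area
#'
#' Step function of the event count over time, normalized to the cell's
#' footprint area and multiplied by the cohort mean footprint area, so cells
#' of different size are comparable: the final value is
#' `n_events * cohort_mean_area / footprint_area`.
#'
#' @param events event data frame from [classify_fusion_events()].
#' @param footprint_area this cell's footprint area (um^2), > 0.
#' @param cohort_mean_area mean footprint area over all cells (um^2), > 0;
#'   defaults to `footprint_area` (raw count scale).
#' @param times optional evaluation time grid (stimulus-relative s); default
#'   is the sorted event times.
#' @return data frame with `time_s` and the non-decreasing normalized
#'   cumulative count `cum_events`; the final value is attached as attribute
#'   `"final"`.
#' @export
cumulative_exocytosis <- function(events, footprint_area,
                                  cohort_mean_area = footprint_area,
                                  times = NULL) {
  if (footprint_area <= 0 || cohort_mean_area <= 0)
    stop("footprint areas must be positive")
  scale <- cohort_mean_area / footprint_area
  et <- sort(events$time_s)
  if (is.null(times)) times <- et
  cum <- vapply(times, function(tt) sum(et <= tt), numeric(1L)) * scale
  out <- data.frame(time_s = times, cum_events = cum)
  attr(out, "final") <- length(et) * scale
  out
}

#' Release probability of footprint vesicles
#'
#' Number of fusion events divided by the total number of vesicles at the
#' footprint.
#'
#' @param n_events number of fusion events.
#' @param n_vesicles total number of vesicles at the footprint, >= 1.
#' @return fraction in `[0, 1]`.
#' @export
release_probability <- function(n_events, n_vesicles) {
  if (n_vesicles < 1L) stop("undefined: no vesicles at the footprint")
  if (n_events < 0 || n_events > n_vesicles)
    stop("'n_events' must lie between 0 and 'n_vesicles'")
  n_events / n_vesicles
}

#' Per-cell exocytosis analysis
#'
#' Convenience wrapper running spot tracking and event classification for
#' one cell and assembling the per-cell summary.
#'
#' @inheritParams track_footprint_spots
#' @param cohort_mean_area cohort mean footprint area (um^2); defaults to
#'   this cell's own area.
#' @return a `CellExocytosisResult` list: detected events, vesicle and event
#'   counts, footprint area, vesicle density (per cohort-normalized area),
#'   the cumulative curve, release probability and responder status.
#' @export
analyze_ldcv_cell <- function(movie, footprint, config = analysis_config(),
                              cohort_mean_area = NULL) {
  spots <- track_footprint_spots(movie, footprint, config)
  events <- classify_fusion_events(spots, config, movie$frame_interval)
  area <- roi_area(footprint, movie$pixel_size)
  if (is.null(cohort_mean_area)) cohort_mean_area <- area
  curve <- cumulative_exocytosis(events, area, cohort_mean_area)
  structure(list(
    spots = spots, events = events,
    n_vesicles = length(spots), n_events = nrow(events),
    footprint_area = area,
    vesicle_density = length(spots) / area * cohort_mean_area,
    cumulative = curve,
    release_probability = if (length(spots) >= 1L)
      release_probability(nrow(events), length(spots)) else NA_real_,
    responder = nrow(events) >= 1L),
    class = "CellExocytosisResult")
}

#' Fraction of cells that underwent exocytosis
#'
#' @param results list of `CellExocytosisResult` objects.
#' @return fraction of cells with at least one fusion event.
#' @export
summarize_responders <- function(results) {
  if (!length(results)) stop("empty result list")
  mean(vapply(results, function(r) isTRUE(r$responder), logical(1L)))
}
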