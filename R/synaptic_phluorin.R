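# Synaptic pHluorin (SypHy) analysis: synapse identification by the NH4Cl
# plateau, pool normalization, 2xSD response-time detection and synchrony
# classification.

#' Identify synapses as immobile puncta with an NH4Cl plateau
#'
#' Puncta are detected on the mean image of the NH4Cl window (where the
#' whole vesicle pool is fluorescent) and kept when they are immobile --
#' centroid drift between the pre-stimulus mean image and the NH4 mean image
#' at most `immobility_tol` pixels -- and respond to NH4Cl with a sharp
#' rise: mean intensity inside the window at least `plateau_factor` times
#' the pre-application mean.
#'
#' @param movie a background-subtracted `MovieStack`.
#' @param nh4_window `(start, end)` of the NH4Cl application in
#'   stimulus-relative seconds; must lie inside the movie span.
#' @param config an [analysis_config()] (supplies `psf_sigma`,
#'   `detect_threshold`, `trace_radius`, `immobility_tol`,
#'   `plateau_factor`).
#' @return a list of disk-shaped `RegionOfInterest` masks, one per accepted
#'   synapse, each carrying attributes `centroid` (0-based (row, col)) and
#'   `plateau_ratio`; the candidate table is attached as attribute
#'   `"candidates"`.
#' @export
identify_synapses <- function(movie, nh4_window, config = analysis_config()) {
  stopifnot(inherits(movie, "MovieStack"))
  times <- frame_times(movie)
  in_win <- times >= nh4_window[1L] & times <= nh4_window[2L]
  if (!any(in_win)) stop("'nh4_window' lies outside the movie span")
  pre_win <- times < nh4_window[1L]
  if (!any(pre_win)) stop("no frames precede the NH4 window")
  d <- dim(movie$frames)
  nh4_mean <- apply(movie$frames[, , in_win, drop = FALSE], c(1L, 2L), mean)
  pre_mean <- apply(movie$frames[, , pre_win, drop = FALSE], c(1L, 2L), mean)
  puncta <- detect_spots(nh4_mean, config$psf_sigma, config$detect_threshold)
  rois <- list()
  cand <- cbind(puncta, drift = NA_real_, plateau_ratio = NA_real_,
                accepted = logical(nrow(puncta)))
  wrad <- ceiling(3 * config$psf_sigma)
  for (i in seq_len(nrow(puncta))) {
    ctr <- c(puncta$row[i], puncta$col[i])
    c_nh4 <- patch_centroid(nh4_mean, ctr, wrad)
    c_pre <- patch_centroid(pre_mean, ctr, wrad)
    drift <- sqrt(sum((c_nh4 - c_pre)^2))
    tr <- disk_trace(movie$frames, ctr, config$trace_radius)
    pre_lvl <- mean(tr[pre_win])
    plateau <- mean(tr[in_win])
    ratio <- if (pre_lvl > 0) plateau / pre_lvl else Inf
    cand$drift[i] <- drift
    cand$plateau_ratio[i] <- ratio
    ok <- drift <= config$immobility_tol && ratio >= config$plateau_factor
    cand$accepted[i] <- ok
    if (ok) {
      px <- disk_pixels(ctr, config$trace_radius, d[1:2])
      mask <- matrix(FALSE, d[1L], d[2L])
      mask[px[, 1L] + 1L + d[1L] * px[, 2L]] <- TRUE
      roi <- roi_mask(mask)
      attr(roi, "centroid") <- ctr
      attr(roi, "plateau_ratio") <- ratio
      rois[[length(rois) + 1L]] <- roi
    }
  }
  attr(rois, "candidates") <- cand
  rois
}

#' Extract per-synapse intensity traces
#'
#' The trace of a synapse is the mean intensity over its ROI pixels in each
#' frame (the movie is assumed background-subtracted).
#'
#' @param movie a background-subtracted `MovieStack`.
#' @param rois list of `RegionOfInterest`, e.g. from [identify_synapses()].
#' @return list of `SynapseTrace` objects with fields `id`, `times`
#'   (stimulus-relative s), `raw` (AU) and `normalized` (`NULL` until
#'   [normalize_to_nh4()] is applied).
#' @export
extract_synapse_traces <- function(movie, rois) {
  stopifnot(inherits(movie, "MovieStack"))
  times <- frame_times(movie)
  d <- dim(movie$frames)
  lapply(seq_along(rois), function(i) {
    mask <- roi_rasterize(rois[[i]], d[1:2])
    idx <- which(mask)
    nhw <- prod(d[1:2])
    raw <- vapply(seq_len(d[3L]),
                  function(t) mean(movie$frames[idx + (t - 1L) * nhw]),
                  numeric(1L))
    structure(list(id = i, times = times, raw = raw, normalized = NULL),
              class = "SynapseTrace")
  })
}

#' Normalize a synapse trace to its NH4Cl-revealed total pool
#'
#' Divides the raw trace by its maximum inside the NH4 window, so the
#' normalized signal is a fraction of the total vesicle pool (exactly 1 at
#' the plateau maximum). This removes the synapse-to-synapse variability of
#' reporter expression: rescaling the raw trace by any positive constant
#' leaves the normalized trace unchanged.
#'
#' @param trace a `SynapseTrace`.
#' @param nh4_window `(start, end)` in stimulus-relative seconds.
#' @return the trace with its `normalized` field filled in.
#' @export
normalize_to_nh4 <- function(trace, nh4_window) {
  stopifnot(inherits(trace, "SynapseTrace"))
  in_win <- trace$times >= nh4_window[1L] & trace$times <= nh4_window[2L]
  if (!any(in_win)) stop("'nh4_window' lies outside the trace span")
  m <- max(trace$raw[in_win])
  if (m <= 0) stop("non-positive NH4 plateau maximum; cannot normalize")
  trace$normalized <- trace$raw / m
  trace$nh4_window <- nh4_window
  trace
}

#' Detect the response time of a synapse trace
#'
#' The response time is the first time at which the trace exceeds its
#' baseline mean by `sd_factor` times the baseline standard deviation,
#' sustained for `sustain_frames` consecutive frames. Baseline statistics
#' are computed over `baseline_window`, which must precede any candidate
#' response and contain at least five samples; the search runs from the end
#' of the baseline window to `search_end` (use the NH4 application start to
#' avoid detecting the plateau itself).
#'
#' @param trace a normalized `SynapseTrace` (falls back on the raw trace if
#'   not normalized).
#' @param baseline_window `(start, end)` of the baseline in
#'   stimulus-relative seconds.
#' @param sd_factor multiple of the baseline SD that must be exceeded.
#' @param search_end last time (stimulus-relative s) considered; defaults to
#'   the start of the trace's NH4 window when known, else the trace end.
#' @param sustain_frames consecutive frames the crossing must persist.
#' @return response time in stimulus-relative seconds, or `NA` if the trace
#'   never crosses. The baseline mean and SD are attached as attributes.
#' @export
detect_response_time <- function(trace, baseline_window = c(-10, -1),
                                 sd_factor = 2, search_end = NULL,
                                 sustain_frames = 2L) {
  stopifnot(inherits(trace, "SynapseTrace"))
  x <- if (!is.null(trace$normalized)) trace$normalized else trace$raw
  tt <- trace$times
  base <- tt >= baseline_window[1L] & tt <= baseline_window[2L]
  if (sum(base) < 5L)
    stop("baseline window holds fewer than 5 samples")
  mu <- mean(x[base]); s <- sd(x[base])
  if (is.null(search_end))
    search_end <- if (!is.null(trace$nh4_window))
      trace$nh4_window[1L] - .Machine$double.eps^0.5 else max(tt)
  cand <- which(tt > baseline_window[2L] & tt <= search_end)
  thr <- mu + sd_factor * s
  above <- x[cand] >= thr
  hit <- NA_real_
  k <- as.integer(sustain_frames)
  if (length(cand) >= k) {
    for (i in seq_len(length(cand) - k + 1L)) {
      if (all(above[i:(i + k - 1L)])) { hit <- tt[cand[i]]; break }
    }
  }
  structure(hit, baseline_mean = mu, baseline_sd = s)
}

#' Classify a response time into the synchrony partition
#'
#' Exhaustive four-way partition: no response is `nonresponsive`; a
#' response before stimulus onset is `pre_stimulus`; within `sync_window`
#' (1 s) of onset is `synchronized`; later is `delayed`.
#'
#' @param response_time stimulus-relative response time (s) or `NA`.
#' @param sync_window synchronization window (s) after onset.
#' @return one of `"nonresponsive"`, `"pre_stimulus"`, `"synchronized"`,
#'   `"delayed"` (vectorized over `response_time`).
#' @export
classify_synchronization <- function(response_time, sync_window = 1.0) {
  vapply(as.numeric(response_time), function(t) {
    if (is.na(t)) "nonresponsive"
    else if (t < 0) "pre_stimulus"
    else if (t <= sync_window) "synchronized"
    else "delayed"
  }, character(1L))
}

#' Peak stimulus-evoked response of a normalized trace
#'
#' Maximum of the normalized trace over the stimulation window, measured
#' above the baseline mean.
#'
#' @param trace a normalized `SynapseTrace`.
#' @param stim_window `(start, end)` of the stimulation period in
#'   stimulus-relative seconds; the window is half-open (`end` excluded) so
#'   an NH4 application starting exactly at `end` does not leak in.
#' @param baseline_window window for the baseline mean.
#' @return peak response in pool-fraction units.
#' @export
peak_response <- function(trace, stim_window, baseline_window = c(-10, -1)) {
  stopifnot(inherits(trace, "SynapseTrace"))
  if (is.null(trace$normalized)) stop("trace must be normalized first")
  tt <- trace$times
  win <- tt >= stim_window[1L] & tt < stim_window[2L]
  if (!any(win)) stop("empty stimulation window")
  base <- tt >= baseline_window[1L] & tt <= baseline_window[2L]
  if (!any(base)) stop("empty baseline window")
  max(trace$normalized[win]) - mean(trace$normalized[base])
}

#' Synchrony composition of a synapse population
#'
#' Fractions of responding synapses that were synchronized, pre-stimulus or
#' delayed (these sum to 1); the nonresponsive fraction of the whole
#' population is reported separately.
#'
#' @param classes character vector of [classify_synchronization()] labels.
#' @return list with `fractions` (named: synchronized, pre_stimulus,
#'   delayed), `n_responders`, `n_total` and `nonresponsive_fraction`.
#' @export
summarize_synchrony <- function(classes) {
  if (!length(classes)) stop("empty class list")
  bad <- setdiff(unique(classes),
                 c("synchronized", "pre_stimulus", "delayed", "nonresponsive"))
  if (length(bad)) stop("unknown class label: ", paste(bad, collapse = ", "))
  resp <- classes[classes != "nonresponsive"]
  if (!length(resp))
    stop("no responding synapses; responder fractions are undefined")
  frac <- vapply(c(synchronized = "synchronized",
                   pre_stimulus = "pre_stimulus", delayed = "delayed"),
                 function(cl) mean(resp == cl), numeric(1L))
  list(fractions = frac, n_responders = length(resp),
       n_total = length(classes),
       nonresponsive_fraction = mean(classes == "nonresponsive"))
}

#' Full SypHy analysis of one movie
#'
#' Identifies synapses, extracts and normalizes their traces, detects
#' response times, classifies synchrony and measures peak responses.
#'
#' @inheritParams identify_synapses
#' @param baseline_window baseline window (stimulus-relative s) for response
#'   detection; must precede any candidate response.
#' @param stim_window stimulation window for the peak response; defaults to
#'   onset up to the NH4 application.
#' @return list with `traces` (normalized `SynapseTrace` list) and `table`
#'   (data frame: synapse_id, response_time_s, class, peak_response).
#' @export
analyze_syphy <- function(movie, nh4_window, config = analysis_config(),
                          baseline_window = config$baseline_window,
                          stim_window = c(0, nh4_window[1L])) {
  rois <- identify_synapses(movie, nh4_window, config)
  traces <- extract_synapse_traces(movie, rois)
  traces <- lapply(traces, normalize_to_nh4, nh4_window = nh4_window)
  rt <- vapply(traces, function(tr)
    as.numeric(detect_response_time(
      tr, baseline_window, config$response_sd_factor,
      sustain_frames = config$response_sustain_frames)), numeric(1L))
  cls <- classify_synchronization(rt, config$sync_window)
  pk <- vapply(traces, peak_response, numeric(1L),
               stim_window = stim_window, baseline_window = baseline_window)
  list(traces = traces,
       table = data.frame(synapse_id = seq_along(traces),
                          response_time_s = rt, class = cls,
                          peak_response = pk))
}
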