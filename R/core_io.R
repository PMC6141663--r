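# Calibrated containers, TIFF I/O, ROI handling and background subtraction.

#' Construct a calibrated fluorescence movie
#'
#' A `MovieStack` bundles a T-frame grayscale time series with its spatial
#' and temporal calibration and the position of stimulus onset on the movie
#' clock. Frames are stored as an H x W x T array; `frames[, , t]` is the
#' t-th acquired image.
#'
#' @param frames numeric array of dimension H x W x T (a single matrix is
#'   treated as a one-frame movie). Values must be finite and non-negative.
#' @param pixel_size pixel edge length in micrometers.
#' @param frame_interval time between consecutive frames in seconds.
#' @param stim_onset time of stimulus onset on the movie clock, in seconds
#'   (frame 1 is acquired at clock time 0).
#' @param channel_label free-text channel description.
#' @return an object of class `MovieStack`.
#' @seealso [read_movie()], [write_movie()], [frame_times()]
#' @export
movie_stack <- function(frames, pixel_size, frame_interval,
                        stim_onset = 0, channel_label = "") {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be an H x W x T array or a matrix")
  if (any(dim(frames) < 1L)) stop("all movie dimensions must be >= 1")
  if (!all(is.finite(frames))) stop("frame intensities must be finite")
  if (min(frames) < 0) stop("frame intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (um/pixel)")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0)
    stop("'frame_interval' must be a single positive number (s/frame)")
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval, stim_onset = stim_onset,
         channel_label = as.character(channel_label)[1L]),
    class = "MovieStack")
}

#' @export
print.MovieStack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "MovieStack: %d frames of %d x %d px | %.4g um/px | %.4g s/frame | stim at %.4g s%s\n",
    d[3L], d[1L], d[2L], x$pixel_size, x$frame_interval, x$stim_onset,
    if (nzchar(x$channel_label)) paste0(" | ", x$channel_label) else ""))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie a `MovieStack`.
#' @return integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[3L]

#' Frame acquisition times
#'
#' Times of each frame. With `relative = TRUE` (default) times are given
#' relative to stimulus onset, so that t = 0 is the onset and negative times
#' are pre-stimulus; otherwise they are raw movie-clock times starting at 0.
#'
#' @param movie a `MovieStack`.
#' @param relative express times relative to `stim_onset`?
#' @return numeric vector of length `n_frames(movie)`, in seconds.
#' @export
frame_times <- function(movie, relative = TRUE) {
  t <- (seq_len(n_frames(movie)) - 1L) * movie$frame_interval
  if (relative) t - movie$stim_onset else t
}

#' Read a grayscale TIFF stack as a calibrated movie
#'
#' Loads a single- or multi-page grayscale TIFF in acquisition order, without
#' any intensity rescaling (integer sample values are kept as stored).
#'
#' @param path path to a TIFF file.
#' @inheritParams movie_stack
#' @return a `MovieStack`.
#' @export
read_movie <- function(path, pixel_size, frame_interval,
                       stim_onset = 0, channel_label = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("cannot read TIFF '", path, "': ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (!is.matrix(pages[[i]]))
      stop("page ", i, " of '", path,
           "' is not grayscale (RGB or multi-sample pages are unsupported)")
    if (i > 1L && !identical(dim(pages[[i]]), dim(pages[[1L]])))
      stop("page ", i, " of '", path, "' has shape ",
           paste(dim(pages[[i]]), collapse = "x"),
           ", expected ", paste(dim(pages[[1L]]), collapse = "x"))
  }
  frames <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  movie_stack(frames, pixel_size, frame_interval, stim_onset, channel_label)
}

#' Write a movie as a multi-page grayscale TIFF
#'
#' Integer-valued stacks round-trip bit-exactly through
#' [write_movie()]/[read_movie()] as long as values fit the sample depth.
#'
#' @param movie a `MovieStack`.
#' @param path output path.
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, bits_per_sample = 16L) {
  stopifnot(inherits(movie, "MovieStack"))
  if (!bits_per_sample %in% c(8L, 16L))
    stop("'bits_per_sample' must be 8 or 16")
  top <- 2^bits_per_sample - 1
  if (max(movie$frames) > top)
    stop("intensities exceed the ", bits_per_sample, "-bit range")
  pages <- lapply(seq_len(n_frames(movie)),
                  function(t) movie$frames[, , t] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Regions of interest

#' Polygonal region of interest
#'
#' Vertices are 0-based, pixel-centered (row, col) coordinates. The polygon
#' must be simple (non-self-intersecting) and have at least three vertices.
#'
#' @param vertices numeric n x 2 matrix of (row, col) vertex coordinates.
#' @return an object of class `RegionOfInterest` (kind `"polygon"`).
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("'vertices' must be an n x 2 matrix")
  if (nrow(vertices) < 3L)
    stop("a polygon ROI needs at least 3 vertices, got ", nrow(vertices))
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (.polygon_self_intersects(vertices))
    stop("polygon is not simple (edges self-intersect)")
  structure(list(kind = "polygon", vertices = unname(vertices)),
            class = "RegionOfInterest")
}

#' Label-mask region of interest
#'
#' @param mask logical (or 0/1) matrix; `TRUE` pixels belong to the ROI.
#' @return an object of class `RegionOfInterest` (kind `"label_mask"`).
#' @export
roi_mask <- function(mask) {
  mask <- if (is.logical(mask)) mask else mask != 0
  if (!is.matrix(mask)) stop("'mask' must be a matrix")
  if (!any(mask)) stop("ROI mask is empty")
  structure(list(kind = "label_mask", mask = mask),
            class = "RegionOfInterest")
}

# segment-intersection test between non-adjacent polygon edges
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  cross <- function(o, a, b)
    (a[1L] - o[1L]) * (b[2L] - o[2L]) - (a[2L] - o[2L]) * (b[1L] - o[1L])
  intersects <- function(p1, p2, p3, p4) {
    d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
    d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
    (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
       ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the closing edge
      if (intersects(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

#' Area of a region of interest
#'
#' Polygon ROIs use the shoelace rule on the vertex coordinates; mask ROIs
#' count member pixels. Both are scaled by `pixel_size^2`.
#'
#' @param roi a `RegionOfInterest`.
#' @param pixel_size pixel edge length in micrometers.
#' @return area in square micrometers.
#' @export
roi_area <- function(roi, pixel_size) {
  stopifnot(inherits(roi, "RegionOfInterest"))
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be positive")
  px <- switch(roi$kind,
    polygon = abs(pracma::polyarea(roi$vertices[, 1L], roi$vertices[, 2L])),
    label_mask = sum(roi$mask))
  px * pixel_size^2
}

#' Rasterize a region of interest to a pixel mask
#'
#' A pixel belongs to the mask when its (0-based) center lies inside the
#' polygon; mask ROIs are padded or cropped to the requested image size.
#'
#' @param roi a `RegionOfInterest`.
#' @param dim image dimensions `c(H, W)`.
#' @return logical H x W matrix.
#' @export
roi_rasterize <- function(roi, dim) {
  stopifnot(inherits(roi, "RegionOfInterest"), length(dim) == 2L)
  h <- dim[1L]; w <- dim[2L]
  if (roi$kind == "label_mask") {
    m <- matrix(FALSE, h, w)
    mh <- min(h, nrow(roi$mask)); mw <- min(w, ncol(roi$mask))
    m[seq_len(mh), seq_len(mw)] <- roi$mask[seq_len(mh), seq_len(mw)]
    return(m)
  }
  bnd <- rbind(roi$vertices, roi$vertices[1L, ])
  centers <- cbind(rep(0:(h - 1L), times = w), rep(0:(w - 1L), each = h))
  inside <- mgcv::in.out(bnd, centers)
  matrix(inside, h, w)
}

## ---------------------------------------------------------------------------
## Background subtraction

# per-frame image mode. Quantized images (most pixels on few levels, e.g.
# clean or uniform frames) use the exact histogram mode; continuous noisy
# frames use the argmax of a kernel density estimate, which is stable where
# a raw histogram argmax is not.
.image_mode <- function(x) {
  x <- as.vector(x)
  u <- round(x)
  tab <- tabulate(u - min(u) + 1L)
  if (max(tab) >= 0.05 * length(u))
    return((which.max(tab) - 1L) + min(u))
  d <- stats::density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Subtract a per-frame scalar background
#'
#' The background of each frame is a single scalar: the mean intensity over
#' `bg_roi` if one is supplied (the ROI should lie outside every cell
#' footprint), otherwise the per-frame image mode. After subtraction,
#' negative intensities are clamped to zero.
#'
#' @param movie a `MovieStack`.
#' @param bg_roi optional `RegionOfInterest` sampling pure background.
#' @return a background-subtracted `MovieStack`.
#' @export
subtract_background <- function(movie, bg_roi = NULL) {
  stopifnot(inherits(movie, "MovieStack"))
  d <- dim(movie$frames)
  mask <- NULL
  if (!is.null(bg_roi)) {
    mask <- roi_rasterize(bg_roi, d[1:2])
    if (!any(mask)) stop("background ROI covers no pixels of the image")
  }
  out <- movie
  for (t in seq_len(d[3L])) {
    fr <- movie$frames[, , t]
    bg <- if (is.null(mask)) .image_mode(fr) else mean(fr[mask])
    out$frames[, , t] <- pmax(fr - bg, 0)
  }
  out
}

## ---------------------------------------------------------------------------
## Analysis configuration

#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults encode the operational criteria used throughout: a full-fusion
#' event must complete within 200 ms, a synapse is synchronized when it
#' responds within 1 s of stimulus onset, a response is a rise of twice the
#' baseline standard deviation, and synapse selection requires puncta
#' 1,000 AU above the adjacent neurite.
#'
#' @param full_fusion_max_duration maximal duration (s) of the intensity drop
#'   that qualifies as full fusion.
#' @param sync_window window (s) after stimulus onset within which a synapse
#'   response counts as synchronized.
#' @param response_sd_factor multiple of the baseline standard deviation a
#'   trace must exceed to count as responding.
#' @param synapse_intensity_delta intensity excess (AU) over the adjacent
#'   neurite required of synaptic puncta in both channels.
#' @param profile_width line-profile width in pixels.
#' @param profile_length line-profile length in micrometers.
#' @param psf_sigma point-spread-function sigma (px) used for detection.
#' @param detect_threshold detection threshold (AU) on the band-pass
#'   (difference-of-Gaussians) response.
#' @param trace_radius radius (px) of the disk over which spot traces are
#'   averaged; defaults to `2 * psf_sigma`.
#' @param full_fusion_high,full_fusion_low fractions of the running-median
#'   baseline defining the start (fall below `high`) and completion (fall to
#'   `low`) of a full-fusion drop.
#' @param full_fusion_nonrecovery time (s) the trace must stay below the
#'   `high` level after the drop.
#' @param kiss_rise_factor transient rise (multiple of baseline) that marks a
#'   kiss-and-run candidate.
#' @param kiss_max_duration maximal duration (s) of the transient rise.
#' @param kiss_width_factor concomitant spot-width increase (multiple of the
#'   baseline width) required of a kiss-and-run event (the released cloud).
#' @param baseline_window pre-stimulus window (s, stimulus-relative) used for
#'   baseline statistics of SypHy traces.
#' @param response_sustain_frames number of consecutive frames a response
#'   crossing must be sustained.
#' @param immobility_tol maximal centroid drift (px) of an immobile punctum.
#' @param plateau_factor minimal ratio of the NH4Cl plateau to the
#'   pre-application mean for a punctum to qualify as a synapse.
#' @return an object of class `AnalysisConfig`.
#' @export
analysis_config <- function(full_fusion_max_duration = 0.2,
                            sync_window = 1.0,
                            response_sd_factor = 2.0,
                            synapse_intensity_delta = 1000,
                            profile_width = 3L,
                            profile_length = 4,
                            psf_sigma = 1.3,
                            detect_threshold = 50,
                            trace_radius = NULL,
                            full_fusion_high = 0.5,
                            full_fusion_low = 0.1,
                            full_fusion_nonrecovery = 1.0,
                            kiss_rise_factor = 1.5,
                            kiss_max_duration = 0.5,
                            kiss_width_factor = 1.3,
                            baseline_window = c(-10, -1),
                            response_sustain_frames = 2L,
                            immobility_tol = 1,
                            plateau_factor = 2) {
  cfg <- list(full_fusion_max_duration = full_fusion_max_duration,
              sync_window = sync_window,
              response_sd_factor = response_sd_factor,
              synapse_intensity_delta = synapse_intensity_delta,
              profile_width = as.integer(profile_width),
              profile_length = profile_length,
              psf_sigma = psf_sigma,
              detect_threshold = detect_threshold,
              trace_radius = if (is.null(trace_radius)) 2 * psf_sigma
                             else trace_radius,
              full_fusion_high = full_fusion_high,
              full_fusion_low = full_fusion_low,
              full_fusion_nonrecovery = full_fusion_nonrecovery,
              kiss_rise_factor = kiss_rise_factor,
              kiss_max_duration = kiss_max_duration,
              kiss_width_factor = kiss_width_factor,
              baseline_window = baseline_window,
              response_sustain_frames = as.integer(response_sustain_frames),
              immobility_tol = immobility_tol,
              plateau_factor = plateau_factor)
  durs <- c(cfg$full_fusion_max_duration, cfg$sync_window,
            cfg$full_fusion_nonrecovery, cfg$kiss_max_duration)
  if (any(durs <= 0)) stop("all durations must be positive")
  if (cfg$response_sd_factor <= 0) stop("'response_sd_factor' must be positive")
  if (cfg$profile_width <= 0 || cfg$profile_length <= 0)
    stop("profile width and length must be positive")
  if (cfg$psf_sigma <= 0) stop("'psf_sigma' must be positive")
  if (cfg$full_fusion_low >= cfg$full_fusion_high)
    stop("'full_fusion_low' must be below 'full_fusion_high'")
  if (length(cfg$baseline_window) != 2L ||
      diff(cfg$baseline_window) <= 0)
    stop("'baseline_window' must be an increasing (start, end) pair")
  structure(cfg, class = "AnalysisConfig")
}
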