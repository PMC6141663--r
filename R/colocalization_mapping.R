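# Two-channel colocalization and synapse mapping: Manders coefficients on
# neurite ROIs, synapse selection by the 1,000-AU rule, aligned line-profile
# averaging with enrichment folds, and synapse density / distance measures.

#' Manders colocalization coefficients
#'
#' Intensity co-occurrence restricted to an ROI:
#' `M1 = sum(A over pixels with B > thrB) / sum(A over pixels with A > thrA)`
#' and symmetrically for `M2`. Thresholds default to 0, appropriate for
#' background-subtracted images; they are recorded in the result.
#'
#' @param channelA,channelB co-registered image matrices of equal shape.
#' @param roi optional `RegionOfInterest` restricting the sums.
#' @param thrA,thrB channel thresholds (AU), >= 0.
#' @return a `MandersResult` list: `M1`, `M2` (`NA` with `undefined = TRUE`
#'   when a denominator is empty), thresholds and `n_pixels`.
#' @export
manders_coefficients <- function(channelA, channelB, roi = NULL,
                                 thrA = 0, thrB = 0) {
  if (!identical(dim(channelA), dim(channelB)))
    stop("channel images must have the same shape")
  if (thrA < 0 || thrB < 0) stop("thresholds must be non-negative")
  mask <- if (is.null(roi)) matrix(TRUE, nrow(channelA), ncol(channelA))
          else roi_rasterize(roi, dim(channelA))
  a <- channelA[mask]; b <- channelB[mask]
  denA <- sum(a[a > thrA]); denB <- sum(b[b > thrB])
  m1 <- if (denA > 0) sum(a[b > thrB]) / denA else NA_real_
  m2 <- if (denB > 0) sum(b[a > thrA]) / denB else NA_real_
  structure(list(M1 = m1, M2 = m2, thrA = thrA, thrB = thrB,
                 n_pixels = sum(mask),
                 undefined = denA <= 0 || denB <= 0),
            class = "MandersResult")
}

#' Select synaptic puncta by dual-channel intensity excess
#'
#' Synapses are puncta in which BOTH markers exceed the local neurite
#' baseline by at least `delta` (1,000 AU) and whose centroids co-localize
#' within `match_radius` pixels. The local baseline of a punctum is the
#' median intensity of its neurite ROI excluding a disk of
#' `exclusion_radius` pixels around the punctum.
#'
#' @param channelA,channelB background-subtracted images of the two synaptic
#'   markers (e.g. a vesicle-membrane and an active-zone marker); puncta are
#'   detected in `channelA` and matched in `channelB`.
#' @param neurite_rois list of `RegionOfInterest` covering the neurites.
#' @param delta required intensity excess (AU) over the neurite baseline.
#' @param config an [analysis_config()] (PSF sigma and detection threshold).
#' @param match_radius maximal centroid separation (px) between channels.
#' @param exclusion_radius radius (px) excluded around a punctum when the
#'   neurite baseline is measured.
#' @return data frame of accepted synapse centroids (`row`, `col`, 0-based,
#'   from channel A) with per-channel intensity excesses; the full candidate
#'   table is attached as attribute `"candidates"`.
#' @export
select_synapses <- function(channelA, channelB, neurite_rois, delta = 1000,
                            config = analysis_config(), match_radius = 2,
                            exclusion_radius = 3) {
  if (!identical(dim(channelA), dim(channelB)))
    stop("channel images must have the same shape")
  d <- dim(channelA)
  nmask <- Reduce(`|`, lapply(neurite_rois, roi_rasterize, dim = d))
  if (!any(nmask)) stop("neurite ROIs cover no pixels")
  pa <- detect_spots(channelA, config$psf_sigma, config$detect_threshold)
  pb <- detect_spots(channelB, config$psf_sigma, config$detect_threshold)
  keep_in <- function(p) {
    if (!nrow(p)) return(p)
    p[nmask[cbind(round(p$row) + 1L, round(p$col) + 1L)], , drop = FALSE]
  }
  pa <- keep_in(pa); pb <- keep_in(pb)
  cand <- data.frame(row = numeric(), col = numeric(),
                     excessA = numeric(), excessB = numeric(),
                     match_dist = numeric(), accepted = logical())
  for (i in seq_len(nrow(pa))) {
    ctr <- c(pa$row[i], pa$col[i])
    # nearest matching punctum in the other channel
    md <- Inf
    if (nrow(pb)) {
      dd <- sqrt((pb$row - ctr[1L])^2 + (pb$col - ctr[2L])^2)
      md <- min(dd)
    }
    # local neurite baseline per channel, punctum excluded
    excl <- disk_pixels(ctr, exclusion_radius, d)
    emask <- nmask
    emask[excl[, 1L] + 1L + d[1L] * excl[, 2L]] <- FALSE
    if (!any(emask)) stop("no neurite baseline pixels around punctum ", i)
    baseA <- median(channelA[emask]); baseB <- median(channelB[emask])
    ri <- round(ctr[1L]) + 1L; ci <- round(ctr[2L]) + 1L
    exA <- channelA[ri, ci] - baseA
    exB <- channelB[ri, ci] - baseB
    ok <- exA >= delta && exB >= delta && md <= match_radius
    cand <- rbind(cand, data.frame(row = ctr[1L], col = ctr[2L],
                                   excessA = exA, excessB = exB,
                                   match_dist = md, accepted = ok))
  }
  out <- cand[cand$accepted, c("row", "col", "excessA", "excessB"),
              drop = FALSE]
  rownames(out) <- NULL
  attr(out, "candidates") <- cand
  out
}

#' Extract an intensity profile along a wide line
#'
#' Samples the image along the polyline at 1-px arclength spacing; at each
#' sample the intensity is the mean of `width` bilinear-interpolated samples
#' spaced 1 px along the local normal. The path must stay inside the image.
#'
#' @param image image matrix.
#' @param path n x 2 matrix of 0-based (row, col) way-points.
#' @param width profile width in pixels (odd widths are symmetric).
#' @param pixel_size micrometers per pixel, used for the position axis.
#' @return data frame with `position_um` (arclength from the path start) and
#'   `intensity`.
#' @export
extract_line_profile <- function(image, path, width = 3L, pixel_size = 1) {
  path <- as.matrix(path)
  if (ncol(path) != 2L || nrow(path) < 2L)
    stop("'path' must be an n x 2 matrix with at least 2 way-points")
  if (width < 1L) stop("'width' must be >= 1")
  seglen <- sqrt(rowSums((path[-1L, , drop = FALSE] -
                            path[-nrow(path), , drop = FALSE])^2))
  total <- sum(seglen)
  if (total <= 0) stop("degenerate path of zero length")
  s <- seq(0, total, by = 1)           # 1-px arclength spacing
  cum <- c(0, cumsum(seglen))
  # map arclength to point and unit tangent
  pts <- matrix(0, length(s), 2L)
  tans <- matrix(0, length(s), 2L)
  for (i in seq_along(s)) {
    j <- max(1L, min(findInterval(s[i], cum, rightmost.closed = TRUE),
                     length(seglen)))
    f <- (s[i] - cum[j]) / seglen[j]
    pts[i, ] <- path[j, ] + f * (path[j + 1L, ] - path[j, ])
    tans[i, ] <- (path[j + 1L, ] - path[j, ]) / seglen[j]
  }
  normals <- cbind(-tans[, 2L], tans[, 1L])
  offsets <- seq_len(width) - (width + 1) / 2
  acc <- numeric(length(s))
  for (o in offsets) {
    rr <- pts[, 1L] + o * normals[, 1L]
    cc <- pts[, 2L] + o * normals[, 2L]
    acc <- acc + bilinear_interp(image, rr, cc)
  }
  data.frame(position_um = s * pixel_size, intensity = acc / width)
}

#' Align line profiles on a reference channel and average
#'
#' Each synapse contributes one profile per channel, all sampled on the same
#' regular grid. Profiles of a synapse are shifted together so that the
#' maximum of the reference channel sits at the grid center (the synapse
#' center); overhanging samples are dropped, and the pointwise mean and SEM
#' are computed per channel over the contributing synapses.
#'
#' @param profiles list of synapses; each synapse is a named list of
#'   channels, each channel a data frame from [extract_line_profile()] (or a
#'   numeric vector on the common grid).
#' @param reference name of the reference channel whose maximum defines the
#'   synapse center.
#' @param spacing_um grid spacing in micrometers (inferred from the first
#'   profile's `position_um` when possible).
#' @return data frame with `position_um` (0 at the aligned center) and, per
#'   channel, `<channel>_mean`, `<channel>_sem` and `<channel>_n`.
#' @export
align_and_average_profiles <- function(profiles, reference,
                                       spacing_um = NULL) {
  if (!length(profiles)) stop("no profiles supplied")
  as_vec <- function(p) if (is.data.frame(p)) p$intensity else as.numeric(p)
  channels <- names(profiles[[1L]])
  if (!reference %in% channels)
    stop("reference channel '", reference, "' missing")
  if (is.null(spacing_um)) {
    p1 <- profiles[[1L]][[1L]]
    spacing_um <- if (is.data.frame(p1) && nrow(p1) > 1L)
      diff(p1$position_um[1:2]) else 1
  }
  L <- length(as_vec(profiles[[1L]][[1L]]))
  center <- (L + 1L) %/% 2L
  shifted <- lapply(profiles, function(syn) {
    if (!all(channels %in% names(syn)))
      stop("all synapses must carry the same channels")
    ref <- as_vec(syn[[reference]])
    if (length(ref) != L) stop("profiles must share one common grid")
    shift <- center - which.max(ref)
    lapply(syn[channels], function(p) {
      v <- as_vec(p)
      out <- rep(NA_real_, L)
      src <- seq_len(L) - shift
      ok <- src >= 1L & src <= L
      out[ok] <- v[src[ok]]
      out
    })
  })
  pos <- (seq_len(L) - center) * spacing_um
  out <- data.frame(position_um = pos)
  for (ch in channels) {
    m <- do.call(cbind, lapply(shifted, `[[`, ch))
    n <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    sem <- apply(m, 1L, function(r) {
      r <- r[!is.na(r)]
      if (length(r) > 1L) sd(r) / sqrt(length(r)) else NA_real_
    })
    mu[n == 0L] <- NA_real_
    out[[paste0(ch, "_mean")]] <- mu
    out[[paste0(ch, "_sem")]] <- sem
    out[[paste0(ch, "_n")]] <- n
  }
  out
}

#' Synaptic enrichment fold of an averaged profile
#'
#' Ratio of the mean intensity within `center_halfwidth` of the aligned
#' synapse center to the mean intensity in the two flanking neurite windows.
#'
#' @param profile data frame with `position_um` and an intensity column
#'   (`intensity`, a `*_mean` column, or the second column).
#' @param center_halfwidth half-width (um) of the central synapse window.
#' @param flank_window `(inner, outer)` distances (um) from the center
#'   defining the flanking neurite windows on both sides; `inner` must be at
#'   least `center_halfwidth`.
#' @return enrichment fold (dimensionless).
#' @export
enrichment_fold <- function(profile, center_halfwidth = 0.5,
                            flank_window = c(0.5, 1.5)) {
  if (flank_window[1L] < center_halfwidth)
    stop("flank window overlaps the center window")
  icol <- intersect(c("intensity", grep("_mean$", names(profile),
                                        value = TRUE)), names(profile))
  if (!length(icol)) icol <- names(profile)[2L]
  v <- profile[[icol[1L]]]
  p <- profile$position_um
  center <- abs(p) <= center_halfwidth
  flank <- abs(p) > flank_window[1L] & abs(p) <= flank_window[2L]
  if (!any(center)) stop("empty center window")
  if (!any(flank & !is.na(v))) stop("empty flank windows")
  fm <- mean(v[flank], na.rm = TRUE)
  if (fm == 0) stop("flank mean is zero; fold undefined")
  mean(v[center], na.rm = TRUE) / fm
}

#' Synapse density per image area
#'
#' @param centroids data frame (or matrix) of synapse centroids, one row per
#'   synapse.
#' @param image_area imaged area in square micrometers, > 0.
#' @return synapses per square micrometer.
#' @export
synapse_density <- function(centroids, image_area) {
  if (image_area <= 0) stop("'image_area' must be positive")
  n <- if (is.null(dim(centroids))) length(centroids) else nrow(centroids)
  n / image_area
}

# distance from a point to a segment (all 0-based pixel coordinates)
.point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - (a + t * ab))^2))
}

#' Distance from a synapse to the nearest soma boundary
#'
#' Minimum Euclidean distance from the centroid to the boundary (plasma
#' membrane) of the nearest soma outline, scaled to micrometers; a centroid
#' inside a soma is at distance 0.
#'
#' @param centroid 0-based (row, col) position in pixels.
#' @param soma_outlines list of soma boundary polygons (n x 2 matrices or
#'   polygon `RegionOfInterest`s).
#' @param pixel_size micrometers per pixel.
#' @return distance in micrometers.
#' @export
nearest_soma_distance <- function(centroid, soma_outlines, pixel_size) {
  if (!length(soma_outlines)) stop("no soma outlines supplied")
  best <- Inf
  for (poly in soma_outlines) {
    v <- if (inherits(poly, "RegionOfInterest")) poly$vertices
         else as.matrix(poly)
    if (nrow(v) < 3L) stop("soma outline needs at least 3 vertices")
    inside <- mgcv::in.out(rbind(v, v[1L, ]),
                           matrix(centroid, 1L, 2L))
    if (inside) return(0)
    n <- nrow(v)
    for (i in seq_len(n)) {
      d <- .point_segment_distance(centroid, v[i, ],
                                   v[if (i == n) 1L else i + 1L, ])
      if (d < best) best <- d
    }
  }
  best * pixel_size
}
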