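# Internal helpers shared across modules.

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Add circular Gaussian spots to an H x W image. `spots` has columns
# row, col (0-based centers), amplitude, sigma. Separable outer-product
# rendering sampled at pixel centers.
render_gaussian_spots <- function(h, w, spots) {
  img <- matrix(0, h, w)
  if (is.null(spots) || nrow(spots) == 0L) return(img)
  rows <- 0:(h - 1L); cols <- 0:(w - 1L)
  for (i in seq_len(nrow(spots))) {
    s <- spots$sigma[i]
    er <- exp(-(rows - spots$row[i])^2 / (2 * s^2))
    ec <- exp(-(cols - spots$col[i])^2 / (2 * s^2))
    img <- img + spots$amplitude[i] * (er %o% ec)
  }
  img
}

# Bilinear interpolation at 0-based continuous (row, col) coordinates.
# Coordinates must lie within [0, H-1] x [0, W-1].
bilinear_interp <- function(image, row, col) {
  h <- nrow(image); w <- ncol(image)
  if (any(row < 0 | row > h - 1 | col < 0 | col > w - 1))
    stop("sample point outside the image")
  r0 <- pmin(floor(row), h - 2); c0 <- pmin(floor(col), w - 2)
  fr <- row - r0; fc <- col - c0
  i00 <- cbind(r0 + 1, c0 + 1)
  (1 - fr) * (1 - fc) * image[i00] +
    fr * (1 - fc) * image[i00 + c(1, 0)] +
    (1 - fr) * fc * image[i00 + c(0, 1)] +
    fr * fc * image[i00 + c(1, 1)]
}

# Indices (and offsets) of pixels within `radius` of a 0-based center.
disk_pixels <- function(center, radius, dim) {
  r0 <- max(0L, floor(center[1L] - radius))
  r1 <- min(dim[1L] - 1L, ceiling(center[1L] + radius))
  c0 <- max(0L, floor(center[2L] - radius))
  c1 <- min(dim[2L] - 1L, ceiling(center[2L] + radius))
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  keep <- (rr - center[1L])^2 + (cc - center[2L])^2 <= radius^2
  cbind(row = rr[keep], col = cc[keep])
}

# Mean intensity within a disk for every frame of a movie.
disk_trace <- function(frames, center, radius) {
  px <- disk_pixels(center, radius, dim(frames)[1:2])
  idx <- px[, 1L] + 1L + nrow(frames) * px[, 2L]
  nhw <- prod(dim(frames)[1:2])
  vapply(seq_len(dim(frames)[3L]),
         function(t) mean(frames[idx + (t - 1L) * nhw]), numeric(1L))
}

# Mean intensity in an annulus (r_in, r_out] around a 0-based center, for
# every frame. Used as a per-spot local background.
annulus_trace <- function(frames, center, r_in, r_out) {
  d <- dim(frames)[1:2]
  px_out <- disk_pixels(center, r_out, d)
  keep <- (px_out[, 1L] - center[1L])^2 + (px_out[, 2L] - center[2L])^2 >
    r_in^2
  px <- px_out[keep, , drop = FALSE]
  if (!nrow(px)) return(numeric(dim(frames)[3L]))
  idx <- px[, 1L] + 1L + nrow(frames) * px[, 2L]
  nhw <- prod(d)
  vapply(seq_len(dim(frames)[3L]),
         function(t) mean(frames[idx + (t - 1L) * nhw]), numeric(1L))
}

# Intensity-weighted centroid of `image` within a square patch of half-size
# `radius` around a 0-based center. Returns c(row, col), 0-based.
patch_centroid <- function(image, center, radius) {
  r0 <- max(0L, round(center[1L] - radius))
  r1 <- min(nrow(image) - 1L, round(center[1L] + radius))
  c0 <- max(0L, round(center[2L] - radius))
  c1 <- min(ncol(image) - 1L, round(center[2L] + radius))
  patch <- image[(r0:r1) + 1L, (c0:c1) + 1L, drop = FALSE]
  patch <- pmax(patch - min(patch), 0)
  tot <- sum(patch)
  if (tot <= 0) return(center)
  rows <- r0:r1; cols <- c0:c1
  c(sum(rowSums(patch) * rows) / tot, sum(colSums(patch) * cols) / tot)
}

# Spot width (Gaussian sigma, px) from the flux ratio of two concentric
# apertures. For an isotropic Gaussian of scale s the flux inside radius r
# is proportional to 1 - exp(-r^2 / (2 s^2)), so the core/outer flux ratio
# q(s) = (1 - exp(-r1^2/2s^2)) / (1 - exp(-r2^2/2s^2)) determines s.
# Because both fluxes are sums over many pixels the estimate averages out
# pixel noise; on noiseless data it is exact. Returns NA where the outer
# flux is not positive.
aperture_width <- function(core_sum, outer_sum, r1, r2) {
  sgrid <- seq(0.2, 8, by = 0.005)
  qgrid <- (1 - exp(-r1^2 / (2 * sgrid^2))) /
    (1 - exp(-r2^2 / (2 * sgrid^2)))      # monotone decreasing in s
  ok <- !duplicated(qgrid)                # drop the saturated q ~ 1 tail
  q <- core_sum / outer_sum
  q[!is.finite(q) | outer_sum <= 0] <- NA_real_
  q <- pmin(pmax(q, min(qgrid)), max(qgrid))
  stats::approx(qgrid[ok], sgrid[ok], xout = q, rule = 2)$y
}

# Causal running median: value i is the median of the preceding `window`
# samples (the sample itself excluded); the first value falls back on itself.
running_median <- function(x, window) {
  n <- length(x)
  out <- numeric(n)
  out[1L] <- x[1L]
  for (i in 2:n) out[i] <- median(x[max(1L, i - window):(i - 1L)])
  out
}
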