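# Correlated elliptical Gaussian morphometry of super-resolution vesicle
# images: model evaluation, moment initialization, bounded least-squares
# fitting and size conversion.

#' Correlated elliptical Gaussian parameters
#'
#' Parameter set of the vesicle intensity model
#' \deqn{f(x, y) = A \exp\!\Big[-\frac{1}{2(1 - cor^2)}\Big(
#'   \big(\tfrac{x - x_0}{x_{width}}\big)^2 +
#'   \big(\tfrac{y - y_0}{y_{width}}\big)^2 -
#'   \frac{2\, cor\, (x - x_0)(y - y_0)}{x_{width}\, y_{width}}
#'   \Big)\Big] + offset}
#' where `x` is the row coordinate and `y` the column coordinate (0-based,
#' pixel-centered). `cor` is the cross-correlation term and must lie strictly
#' between -1 and 1.
#'
#' Note on naming: `x_width`/`y_width` enter the exponent as Gaussian scale
#' parameters, so the model value at `x0 + x_width` (with `cor = 0`) is
#' `A * exp(-1/2)`, about 0.607 A -- not half maximum. The field's customary
#' label for these parameters is "half width at half maximum", and the size
#' conversion in [vesicle_size()] keeps that convention (FWHM = 2 * width),
#' but the formula above is what is evaluated and fitted.
#'
#' @param A peak amplitude (AU), > 0.
#' @param x0,y0 center coordinates (px).
#' @param x_width,y_width axis widths (px), > 0.
#' @param cor cross-correlation term, in (-1, 1).
#' @param offset additive baseline (AU); 0 restricts the model to the pure
#'   Gaussian form.
#' @return an object of class `EllipticalGaussianParams`.
#' @export
elliptical_gaussian <- function(A, x0, y0, x_width, y_width, cor = 0,
                                offset = 0) {
  if (!is.finite(A) || A <= 0) stop("'A' must be positive")
  if (x_width <= 0 || y_width <= 0) stop("widths must be positive")
  if (!is.finite(cor) || abs(cor) >= 1)
    stop("'cor' must lie strictly between -1 and 1")
  structure(list(A = A, x0 = x0, y0 = y0, x_width = x_width,
                 y_width = y_width, cor = cor, offset = offset),
            class = "EllipticalGaussianParams")
}

#' Evaluate the correlated elliptical Gaussian model
#'
#' @param params an `EllipticalGaussianParams` (or a plain list with the same
#'   fields).
#' @param x,y coordinates at which to evaluate (recycled against each other);
#'   `x` is the row coordinate, `y` the column coordinate.
#' @return model values (AU), same length as `x`/`y`.
#' @export
eval_gaussian2d <- function(params, x, y) {
  p <- params
  if (abs(p$cor) >= 1) stop("'cor' must lie strictly between -1 and 1")
  dx <- (x - p$x0) / p$x_width
  dy <- (y - p$y0) / p$y_width
  q <- dx^2 + dy^2 - 2 * p$cor * dx * dy
  p$A * exp(-q / (2 * (1 - p$cor^2))) + (if (is.null(p$offset)) 0 else p$offset)
}

# Render the model on a full 0-based pixel grid.
render_gaussian2d <- function(params, h, w) {
  rows <- matrix(0:(h - 1L), h, w)
  cols <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  matrix(eval_gaussian2d(params, rows, cols), h, w)
}

#' Moment-based initial estimate for a vesicle fit
#'
#' Amplitude is max minus median, the center is the intensity centroid, the
#' axis widths come from the second central moments, and the correlation
#' from the mixed moment (clipped to (-0.95, 0.95)).
#'
#' @param patch numeric matrix containing one vesicle.
#' @return an `EllipticalGaussianParams` suitable as a fit start.
#' @export
moments_init <- function(patch) {
  if (!is.matrix(patch)) stop("'patch' must be a matrix")
  med <- median(patch)
  A <- max(patch) - med
  if (A <= 0) stop("flat patch: no peak above the median level")
  wgt <- pmax(patch - med, 0)
  tot <- sum(wgt)
  rows <- matrix(0:(nrow(patch) - 1L), nrow(patch), ncol(patch))
  cols <- matrix(0:(ncol(patch) - 1L), nrow(patch), ncol(patch), byrow = TRUE)
  x0 <- sum(wgt * rows) / tot
  y0 <- sum(wgt * cols) / tot
  mxx <- sum(wgt * (rows - x0)^2) / tot
  myy <- sum(wgt * (cols - y0)^2) / tot
  mxy <- sum(wgt * (rows - x0) * (cols - y0)) / tot
  cor <- mxy / sqrt(mxx * myy)
  cor <- max(min(cor, 0.95), -0.95)
  elliptical_gaussian(A = A, x0 = x0, y0 = y0,
                      x_width = max(sqrt(mxx), 0.31),
                      y_width = max(sqrt(myy), 0.31),
                      cor = cor, offset = med)
}

#' Fit the correlated elliptical Gaussian to a vesicle patch
#'
#' Bounded Levenberg-Marquardt least squares of [eval_gaussian2d()] over the
#' patch, started from [moments_init()] unless an initial parameter set is
#' supplied. `cor` is constrained to (-0.99, 0.99) and widths to > 0.3 px.
#'
#' @param patch numeric matrix, at least 7 x 7 px.
#' @param init optional `EllipticalGaussianParams` start value.
#' @param fit_offset estimate an additive baseline? With `FALSE` the offset
#'   is pinned to 0 (the pure model as printed).
#' @param max_iter maximal number of optimizer iterations.
#' @return a list with elements `params` (`EllipticalGaussianParams`) and
#'   `diagnostics` (residual sum of squares, convergence flag, iteration
#'   count, parameter standard errors).
#' @export
fit_vesicle <- function(patch, init = NULL, fit_offset = TRUE,
                        max_iter = 200L) {
  if (!is.matrix(patch)) stop("'patch' must be a matrix")
  if (nrow(patch) < 7L || ncol(patch) < 7L)
    stop("patch must be at least 7 x 7 px, got ",
         nrow(patch), " x ", ncol(patch))
  if (diff(range(patch)) == 0) stop("all-equal patch cannot be fitted")
  if (is.null(init)) init <- moments_init(patch)
  h <- nrow(patch); w <- ncol(patch)
  rows <- matrix(0:(h - 1L), h, w)
  cols <- matrix(0:(w - 1L), h, w, byrow = TRUE)

  par0 <- c(A = init$A, x0 = init$x0, y0 = init$y0,
            x_width = init$x_width, y_width = init$y_width, cor = init$cor)
  lower <- c(A = 1e-9, x0 = -2, y0 = -2, x_width = 0.3, y_width = 0.3,
             cor = -0.99)
  upper <- c(A = Inf, x0 = h + 1, y0 = w + 1, x_width = 4 * h,
             y_width = 4 * w, cor = 0.99)
  if (fit_offset) {
    par0 <- c(par0, offset = init$offset)
    lower <- c(lower, offset = -Inf)
    upper <- c(upper, offset = Inf)
  }
  resid_fn <- function(p) {
    pl <- as.list(p)
    if (!fit_offset) pl$offset <- 0
    eval_gaussian2d(pl, rows, cols) - patch
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-12, ptol = 1e-12))
  p <- as.list(fit$par)
  if (!fit_offset) p$offset <- 0
  # a credible vesicle must be resolvable within the patch: width estimates
  # that grow to the patch scale mean the optimizer fitted a sloping plane,
  # not a punctum
  converged <- fit$info %in% 1:4 && p$A > 1e-6 &&
    p$x_width < nrow(patch) && p$y_width < ncol(patch)
  se <- tryCatch(sqrt(diag(solve(fit$hessian)) * fit$deviance /
                        max(1L, length(patch) - length(par0))),
                 error = function(e) rep(NA_real_, length(par0)))
  params <- tryCatch(
    elliptical_gaussian(p$A, p$x0, p$y0, p$x_width, p$y_width, p$cor,
                        p$offset),
    error = function(e) { converged <<- FALSE; p })
  list(params = params,
       diagnostics = list(rss = fit$deviance, converged = converged,
                          iterations = fit$niter,
                          std_errors = setNames(se, names(par0))))
}

#' Vesicle size from fitted parameters
#'
#' Converts fitted widths to physical size: per-axis full width
#' `FWHM_axis = 2 * width_axis * pixel_size` and the mean half width
#' `(x_width + y_width) / 2 * pixel_size`, both reported in nanometers.
#'
#' @param params an `EllipticalGaussianParams`, or the result of
#'   [fit_vesicle()] (in which case an unconverged fit is an error).
#' @param pixel_size pixel edge length in micrometers.
#' @return a list with `mean_hwhm_nm`, `fwhm_x_nm`, `fwhm_y_nm`.
#' @export
vesicle_size <- function(params, pixel_size) {
  if (!is.null(params$diagnostics)) {
    if (!isTRUE(params$diagnostics$converged))
      stop("refusing to report a size from an unconverged fit")
    params <- params$params
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be positive")
  nm <- pixel_size * 1000
  list(mean_hwhm_nm = (params$x_width + params$y_width) / 2 * nm,
       fwhm_x_nm = 2 * params$x_width * nm,
       fwhm_y_nm = 2 * params$y_width * nm)
}
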