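# Ratiometric Fura-2 calcium: 350/380 ratio images and conversion to
# concentration with an in-situ calibration.

#' Fura-2 in-situ calibration constants
#'
#' Calibration of the ratiometric conversion
#' `[Ca2+] = K_d * beta * (R - R_min) / (R_max - R)`. The defaults are an
#' in-situ whole-cell calibration (`R_max` 3.73, `R_min` 0.64, `K_d` 350 nM,
#' `beta` 6.73, where `beta` is the 380-nm fluorescence ratio
#' F380_min/F380_max).
#'
#' @param R_max ratio at saturating calcium, > `R_min`.
#' @param R_min ratio at zero calcium, > 0.
#' @param K_d Fura-2 dissociation constant in nM, > 0.
#' @param beta F380(min)/F380(max), > 0.
#' @return an object of class `FuraCalibration`.
#' @export
fura_calibration <- function(R_max = 3.73, R_min = 0.64, K_d = 350,
                             beta = 6.73) {
  if (!(R_max > R_min && R_min > 0)) stop("need R_max > R_min > 0")
  if (K_d <= 0) stop("'K_d' must be positive")
  if (beta <= 0) stop("'beta' must be positive")
  structure(list(R_max = R_max, R_min = R_min, K_d = K_d, beta = beta),
            class = "FuraCalibration")
}

#' Background-subtracted 350/380 ratio image
#'
#' `R = (f350 - bg350) / (f380 - bg380)` wherever the denominator is at
#' least `min_f380`; other pixels are masked (`NA` ratio, `valid = FALSE`)
#' rather than extrapolated.
#'
#' @param f350,f380 image matrices of equal shape (350 nm and 380 nm
#'   excitation).
#' @param bg350,bg380 scalar backgrounds (AU).
#' @param min_f380 minimal background-subtracted 380 nm intensity (AU) for a
#'   pixel to be considered valid, > 0.
#' @return list with `ratio` (matrix, `NA` where masked) and `valid`
#'   (logical matrix).
#' @export
ratio_image <- function(f350, f380, bg350 = 0, bg380 = 0, min_f380 = 1) {
  if (!identical(dim(f350), dim(f380)))
    stop("'f350' and 'f380' must have the same shape")
  if (min_f380 <= 0) stop("'min_f380' must be positive")
  den <- f380 - bg380
  valid <- den >= min_f380
  R <- (f350 - bg350) / den
  R[!valid] <- NA_real_
  list(ratio = R, valid = valid)
}

#' Convert a fluorescence ratio to calcium concentration
#'
#' `[Ca2+] = K_d * beta * (R - R_min) / (R_max - R)` in nM. Ratios at or
#' above `R_max` are saturated: they are masked (`NA`) rather than reported
#' as a capped value. Ratios below `R_min` (noise) clamp to 0 nM. Both
#' conditions are flagged.
#'
#' @param R numeric ratio(s); `NA`s propagate.
#' @param calib a [fura_calibration()].
#' @return calcium concentration(s) in nM, same shape as `R`, with logical
#'   attributes `saturated` and `below_rmin`.
#' @export
calcium_from_ratio <- function(R, calib = fura_calibration()) {
  stopifnot(inherits(calib, "FuraCalibration"))
  saturated <- !is.na(R) & R >= calib$R_max
  below <- !is.na(R) & R < calib$R_min
  ca <- calib$K_d * calib$beta * (R - calib$R_min) / (calib$R_max - R)
  ca[saturated] <- NA_real_
  ca[below] <- 0
  structure(ca, saturated = saturated, below_rmin = below)
}

#' Calcium concentration image from a Fura-2 pair
#'
#' Convenience wrapper: [ratio_image()] then [calcium_from_ratio()].
#'
#' @inheritParams ratio_image
#' @param calib a [fura_calibration()].
#' @return list with `ca` (nM matrix), `ratio`, `valid`, `saturated` and
#'   `below_rmin` matrices.
#' @export
calcium_image <- function(f350, f380, calib = fura_calibration(),
                          bg350 = 0, bg380 = 0, min_f380 = 1) {
  ri <- ratio_image(f350, f380, bg350, bg380, min_f380)
  ca <- calcium_from_ratio(ri$ratio, calib)
  list(ca = matrix(as.numeric(ca), nrow(ri$ratio)),
       ratio = ri$ratio, valid = ri$valid,
       saturated = matrix(attr(ca, "saturated"), nrow(ri$ratio)),
       below_rmin = matrix(attr(ca, "below_rmin"), nrow(ri$ratio)))
}
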