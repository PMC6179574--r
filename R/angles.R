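#' Orientation angle utilities
#'
#' Grating orientation lives on a half-circle: it is periodic over 180 degrees,
#' measured clockwise from vertical, and represented in the half-open interval
#' \[0, 180). Circular statistics, however, operate on quantities that are
#' periodic over 360 degrees (2*pi radians). The standard remedy is *angle
#' doubling*: map an orientation of x degrees to 2x degrees on the full circle,
#' do all circular arithmetic there, and halve at the end. These helpers
#' centralize that bookkeeping so the convention lives in exactly one place.
#'
#' @param deg orientation(s) in degrees.
#' @param rad doubled-space angle(s) in radians.
#' @name orientation-angles
NULL

#' @describeIn orientation-angles wrap degrees into \[0, 180).
#' @export
wrap_orientation <- function(deg) {
  ((deg %% 180) + 180) %% 180
}

#' @describeIn orientation-angles orientation degrees to doubled-space radians
#'   (x degrees -> 2x * pi/180 radians).
#' @export
orientation_to_doubled_rad <- function(deg) {
  deg * pi / 90
}

#' @describeIn orientation-angles doubled-space radians back to orientation
#'   degrees in \[0, 180).
#' @export
doubled_rad_to_orientation <- function(rad) {
  wrap_orientation(rad * 90 / pi)
}

#' Circular distance between orientations
#'
#' Smallest absolute angular difference between two orientations, respecting
#' the 180-degree period. The result lies in \[0, 90\].
#'
#' @param a,b orientations in degrees.
#' @return absolute circular differences in degrees.
#' @export
orientation_distance <- function(a, b) {
  d <- abs(wrap_orientation(a) - wrap_orientation(b))
  pmin(d, 180 - d)
}

#' Circular RMSE of decoded orientations
#'
#' Root-mean-square of the circular orientation error, in degrees. Used for
#' parameter-recovery checks of the encoding decoder.
#'
#' @param theta decoded orientations, degrees.
#' @param phi true orientations, degrees.
#' @return scalar RMSE in degrees, in \[0, 90\].
#' @export
circular_rmse <- function(theta, phi) {
  sqrt(mean(orientation_distance(theta, phi)^2))
}
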