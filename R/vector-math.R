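#' Convert a signed cylinder reading to positive-cylinder notation
#'
#' Clinical cylinder can be written in positive (+ve) or negative (-ve)
#' notation; both describe the same astigmatic correction. Negative-cylinder
#' readings are converted by taking the absolute value of the magnitude and
#' flipping the axis by 90 degrees. Axes are reported in the `(0, 180]`
#' convention: the 0-degree meridian is written as 180 (so `-2.00 x 90`
#' becomes `+2.00 x 180`, and `-1.00 x 180` becomes `+1.00 x 90`).
#'
#' @param magnitude Numeric vector of signed cylinder magnitudes in diopters.
#' @param axis Numeric vector of axes in degrees, in `[0, 180]`.
#' @return A tibble with columns `magnitude` (>= 0, diopters) and `axis`
#'   (degrees in `(0, 180]`).
#' @examples
#' to_positive_cylinder(-2, 90)   # +2.00 x 180
#' to_positive_cylinder(-1, 180)  # +1.00 x 90
#' @export
to_positive_cylinder <- function(magnitude, axis) {
  stopifnot(is.numeric(magnitude), is.numeric(axis),
            length(magnitude) == length(axis))
  if (any(!is.finite(magnitude)) || any(!is.finite(axis))) {
    stop("cylinder magnitude and axis must be finite")
  }
  if (any(axis < 0 | axis > 180)) {
    stop("axis must lie in [0, 180] degrees")
  }
  neg <- magnitude < 0
  out_axis <- ifelse(neg, axis + 90, axis)
  tibble::tibble(
    magnitude = abs(magnitude),
    axis = wrap_axis(out_axis)
  )
}

# Map any axis onto the (0, 180] half-turn; 0 and 180 are the same meridian
# and are reported as 180.
wrap_axis <- function(axis) {
  a <- axis %% 180
  a[a == 0] <- 180
  a
}

#' Mirror left-eye (OS) axes about the vertical meridian
#'
#' Left-eye axes are reflected (`180 - axis`) before analysis so that
#' symmetric errors from cyclotorsion or asymmetric healing do not cancel
#' when right and left eyes are averaged together. Right-eye (OD) axes are
#' unchanged. A mirrored result of 0 is reported as 180.
#'
#' @param axis Numeric vector of axes in degrees, in `(0, 180]`.
#' @param eye Character vector of `"OD"`/`"OS"` labels (recycled if scalar).
#' @return Numeric vector of mirrored axes in `(0, 180]`.
#' @export
mirror_os_axis <- function(axis, eye) {
  stopifnot(is.numeric(axis), is.character(eye))
  if (length(eye) == 1L) eye <- rep(eye, length(axis))
  stopifnot(length(eye) == length(axis))
  eye <- toupper(eye)
  if (!all(eye %in% c("OD", "OS"))) stop("eye labels must be 'OD' or 'OS'")
  if (any(axis <= 0 | axis > 180)) stop("axis must lie in (0, 180] degrees")
  ifelse(eye == "OS", wrap_axis(180 - axis), axis)
}

#' Double-angle decomposition of astigmatism vectors
#'
#' Astigmatism is a 180-degree-periodic quantity: an axis of 0 and an axis
#' of 180 are the same meridian. Doubling the angle maps it onto an ordinary
#' 360-degree plane where astigmatism vectors add and subtract component-wise:
#' `x = M cos(2 theta)`, `y = M sin(2 theta)`.
#'
#' @param magnitude Numeric vector of magnitudes (diopters, >= 0).
#' @param axis Numeric vector of axes in degrees, in `(0, 180]`.
#' @return A tibble with columns `x` and `y` (diopters on the doubled-angle
#'   plane).
#' @seealso [rect_to_polar()] for the inverse.
#' @export
polar_to_rect <- function(magnitude, axis) {
  stopifnot(is.numeric(magnitude), is.numeric(axis),
            length(magnitude) == length(axis))
  # cospi/sinpi keep the cardinal meridians exact (cospi(1) == -1).
  tibble::tibble(
    x = magnitude * cospi(axis / 90),
    y = magnitude * sinpi(axis / 90)
  )
}

#' Recover a polar astigmatism vector from doubled-angle components
#'
#' Inverse of [polar_to_rect()]: `magnitude = sqrt(x^2 + y^2)` and
#' `axis = atan2(y, x) / 2` wrapped into `(0, 180]`. The zero vector maps to
#' magnitude 0 with axis 180 by convention (the axis carries no information).
#'
#' @param x,y Numeric vectors of doubled-angle components (diopters).
#' @return A tibble with columns `magnitude` and `axis`.
#' @export
rect_to_polar <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("rectangular components must be finite")
  }
  magnitude <- sqrt(x^2 + y^2)
  axis <- wrap_axis((atan2(y, x) * 90 / pi) %% 180)
  axis[magnitude == 0] <- 180
  tibble::tibble(magnitude = magnitude, axis = axis)
}

#' Classify an axis as with-the-rule, against-the-rule, or oblique
#'
#' Orientation sectors follow the shaded bands of the standard single-angle
#' plots: against-the-rule (ATR) spans 0--30 and 150--180 degrees, with-the-rule
#' (WTR) spans 60--120 degrees, and the unshaded oblique bands span 30--60 and
#' 120--150 degrees. Exact boundary values (30, 60, 120, 150) are rare
#' measurement artifacts; by default they are assigned to the unshaded
#' oblique label (`boundary = "oblique"`). Set `boundary = "shaded"` to
#' assign them to the adjacent shaded sector instead.
#'
#' @param axis Numeric vector of axes in degrees, in `(0, 180]`.
#' @param boundary Tie-break policy for axes exactly on a sector boundary.
#' @return Factor vector with levels `ATR`, `WTR`, `oblique`; exactly one
#'   label per axis.
#' @export
classify_orientation <- function(axis, boundary = c("oblique", "shaded")) {
  boundary <- match.arg(boundary)
  stopifnot(is.numeric(axis))
  if (any(axis <= 0 | axis > 180)) stop("axis must lie in (0, 180] degrees")
  lab <- rep("oblique", length(axis))
  if (boundary == "oblique") {
    lab[(axis > 0 & axis < 30) | (axis > 150 & axis <= 180)] <- "ATR"
    lab[axis > 60 & axis < 120] <- "WTR"
  } else {
    lab[(axis > 0 & axis <= 30) | (axis >= 150 & axis <= 180)] <- "ATR"
    lab[axis >= 60 & axis <= 120] <- "WTR"
  }
  factor(lab, levels = c("ATR", "WTR", "oblique"))
}
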