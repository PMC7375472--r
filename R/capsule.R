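#' Capsule (stadium) geometry
#'
#' A tubuloid structure is modelled in 2-D as a capsule: a `width_um` by
#' `length_um - width_um` rectangle capped by two semicircles of diameter
#' `width_um`. At `length_um == width_um` the capsule degrades continuously to
#' a disk, so spheroids and slit-lumen tubules share one parameterization.
#' The lumen is the inward offset of the outer capsule: a capsule of width
#' `lumen_fraction * width_um` and length `length_um - (1 - lumen_fraction) *
#' width_um` sharing the same centreline, which leaves a uniform wall all
#' around (circular lumen for disks, slit-like lumen for elongated capsules).
#'
#' @param width_um minor (transverse) dimension in micrometres; must be > 0.
#' @param length_um major dimension in micrometres; must be >= `width_um`.
#' @param lumen_fraction lumen width as a fraction of structure width, in
#'   `[0, 0.9)`; 0 means no lumen (solid structure).
#' @return `capsule_filled_area()`: area of the outer capsule (lumen
#'   included), in square micrometres. `capsule_lumen_area()`: area of the
#'   lumen capsule. `capsule_area()`: wall area, i.e. filled minus lumen.
#' @examples
#' capsule_area(50, 250)            # 50*200 + pi*25^2 = 11963.5
#' capsule_filled_area(100, 100)    # disk of diameter 100
#' @export
capsule_filled_area <- function(width_um, length_um) {
  check_capsule_dims(width_um, length_um)
  width_um * (length_um - width_um) + pi * (width_um / 2)^2
}

#' @rdname capsule_filled_area
#' @export
capsule_lumen_area <- function(width_um, length_um, lumen_fraction) {
  check_capsule_dims(width_um, length_um)
  stopifnot(all(lumen_fraction >= 0), all(lumen_fraction < 0.9))
  lf <- lumen_fraction
  lf * width_um * (length_um - width_um) + pi * (lf * width_um / 2)^2
}

#' @rdname capsule_filled_area
#' @export
capsule_area <- function(width_um, length_um, lumen_fraction = 0) {
  capsule_filled_area(width_um, length_um) -
    capsule_lumen_area(width_um, length_um, lumen_fraction)
}

#' Axis-aligned bounding box of a rotated capsule
#'
#' The capsule centreline segment has length `length_um - width_um`; rotating
#' it by `orientation_rad` gives bounding-box extents
#' `(L - w)|cos theta| + w` by `(L - w)|sin theta| + w`. These are the
#' dimensions a drawn axis-aligned ROI would record.
#'
#' @inheritParams capsule_filled_area
#' @param orientation_rad in-plane rotation of the major axis, radians.
#' @return list with `width_um` (x extent) and `height_um` (y extent).
#' @export
capsule_bbox <- function(width_um, length_um, orientation_rad = 0) {
  check_capsule_dims(width_um, length_um)
  seg <- length_um - width_um
  list(width_um  = seg * abs(cos(orientation_rad)) + width_um,
       height_um = seg * abs(sin(orientation_rad)) + width_um)
}

check_capsule_dims <- function(width_um, length_um) {
  if (any(!is.finite(width_um)) || any(width_um <= 0))
    stop("width_um must be positive and finite")
  if (any(!is.finite(length_um)) || any(length_um < width_um))
    stop("length_um must be finite and >= width_um")
  invisible(TRUE)
}
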