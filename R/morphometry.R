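#' Spherical-like reference area of a structure
#'
#' From a structure's axis-aligned bounding box, the reference area a
#' perfectly spherical (circular in projection) structure of the same minor
#' dimension would have. Two conventions are provided:
#'
#' * `"normalized"` (default): the inscribed disk of diameter
#'   `min(width, height)`, i.e. `r = min(w, h) / 2`, `A_s = pi r^2`. Under
#'   this convention a perfect disk scores agreement exactly 1.
#' * `"as_printed"`: the literal published recipe, `r = min(w, h)` (the full
#'   shortest dimension) and `A_s = 2 pi r^2`. No disk can attain agreement 1
#'   under this reading; it is retained for transparency.
#'
#' @param width_um,height_um bounding-box dimensions in micrometres, > 0.
#' @param convention `"normalized"` or `"as_printed"`.
#' @return list with `r_um` and `spherical_like_area_um2` (vectorised).
#' @export
spherical_like_area <- function(width_um, height_um,
                                convention = c("normalized", "as_printed")) {
  convention <- match.arg(convention)
  if (any(width_um <= 0) || any(height_um <= 0))
    stop("width_um and height_um must be positive")
  m <- pmin(width_um, height_um)
  if (convention == "normalized") {
    r <- m / 2
    As <- pi * r^2
  } else {
    r <- m
    As <- 2 * pi * r^2
  }
  list(r_um = r, spherical_like_area_um2 = As)
}

#' Spherical agreement score
#'
#' The 0-1 morphometric index of likeness to a sphere: 1 for a structure
#' whose measured area equals the reference disk area (cyst/spheroid-like),
#' 0 for strongly elongated tubule-like structures. Computed as the percent
#' difference `d = |A - A_s| / A_s` between the measured area `A` and the
#' spherical-like reference area `A_s`, mapped to `S = 1 - d` and clamped to
#' `[0, 1]` so arbitrarily long tubules saturate at 0.
#'
#' @inheritParams spherical_like_area
#' @param area_um2 measured structure area (um^2); for drawn-ROI-style
#'   measurements this is the full region area, lumen included.
#' @param denominator `"reference"` (divide by `A_s`, default) or
#'   `"measured"` (divide by `A`).
#' @return data.frame (vectorised) with columns `r_um`,
#'   `spherical_like_area_um2`, `percent_difference`, `agreement`,
#'   `convention`.
#' @examples
#' spherical_agreement(100, 100, pi * 50^2)     # exact disk: agreement 1
#' spherical_agreement(50, 250, 11963.5)        # long tubule: clamped to 0
#' @export
spherical_agreement <- function(width_um, height_um, area_um2,
                                convention = c("normalized", "as_printed"),
                                denominator = c("reference", "measured")) {
  convention <- match.arg(convention)
  denominator <- match.arg(denominator)
  if (any(area_um2 <= 0)) stop("area_um2 must be positive")
  if (any(area_um2 > width_um * height_um * (1 + 1e-9)))
    stop("area_um2 exceeds bounding-box area; invalid geometry")
  ref <- spherical_like_area(width_um, height_um, convention)
  denom <- if (denominator == "reference") ref$spherical_like_area_um2 else area_um2
  d <- abs(area_um2 - ref$spherical_like_area_um2) / denom
  S <- pmin(1, pmax(0, 1 - d))
  data.frame(r_um = ref$r_um,
             spherical_like_area_um2 = ref$spherical_like_area_um2,
             percent_difference = d, agreement = S,
             convention = convention, stringsAsFactors = FALSE)
}

#' Before/after change in spherical agreement
#'
#' Signed change for one tracked structure; positive values mean the
#' structure became more cyst-like.
#'
#' @param before,after MorphoScore rows (as returned by
#'   [spherical_agreement()]) for the same structure under the same
#'   convention.
#' @return numeric `after$agreement - before$agreement`.
#' @export
agreement_delta <- function(before, after) {
  if (!identical(as.character(before$convention),
                 as.character(after$convention)))
    stop("before/after scores use different conventions")
  after$agreement - before$agreement
}
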