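#' Default rendering intensities (16-bit scale)
#'
#' Bright-field is rendered as a bright-object-on-dark proxy: structure walls
#' at `bf_fg`, background and lumen at `bf_bg`, so every lumen is an enclosed
#' intensity hole. Fluorescence channels put reporter signal on structure
#' wall pixels over a dim background.
#' @return named list of intensity levels and the default additive Gaussian
#'   noise standard deviation.
#' @export
render_defaults <- function() {
  list(bf_bg = 6000, bf_fg = 26000, fluor_bg = 500, fluor_fg = 20000,
       noise_sd = 800, max_intensity = 65535)
}

#' Render one field of view at one timepoint
#'
#' Rasterises each structure's capsule onto a pixel grid. Wall pixels (between
#' the lumen and outer capsule boundary) are bright in the bright-field
#' channel; lumen pixels stay at background, producing an enclosed hole.
#' Differentiated structures carry membrane reporter signal: red on
#' non-converted wall pixels and, for converted structures, green on a
#' per-pixel Bernoulli(`mosaic_green_fraction`) subset (the remainder stays
#' red, emulating mosaic recombination). Prestructures carry no reporter.
#'
#' @param truth_t truth rows for a single timepoint (one row per structure),
#'   as produced by [generate_field_structures()] or [simulate_timecourse()].
#' @param field_um numeric length-2 field extent (x, y) in micrometres.
#' @param pixel_size_um micrometres per pixel; must be > 0.
#' @param noise_sd additive Gaussian noise sd (intensity units); 0 for
#'   noise-free renders.
#' @param mosaic_green_fraction fraction of converted structures' reporter
#'   pixels rendered green.
#' @param blur_sigma_px optional numeric vector (one per structure) of
#'   Gaussian defocus sigmas in pixels; 0 = in focus. Simulates structures
#'   out of the plane of focus.
#' @param intensities see [render_defaults()].
#' @return object of class `field_image`: list with 16-bit-scale matrices
#'   `brightfield`, `red`, `green` (dim = pixels x, y), integer `labels`
#'   ground-truth mask (structure_id per pixel, wall and lumen), plus
#'   `pixel_size_um`, `timepoint_h`, and the input truth with a
#'   `border_clipped` flag updated from the actual raster extent.
#' @export
render_field <- function(truth_t, field_um = c(2200, 2200),
                         pixel_size_um = 1.6, noise_sd = NULL,
                         mosaic_green_fraction = 0.85,
                         blur_sigma_px = NULL,
                         intensities = render_defaults()) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (is.null(noise_sd)) noise_sd <- intensities$noise_sd
  if (is.null(blur_sigma_px)) blur_sigma_px <- rep(0, nrow(truth_t))
  stopifnot(length(blur_sigma_px) == nrow(truth_t))
  nx <- ceiling(field_um[1] / pixel_size_um)
  ny <- ceiling(field_um[2] / pixel_size_um)
  bf <- matrix(intensities$bf_bg, nx, ny)
  red <- matrix(intensities$fluor_bg, nx, ny)
  green <- matrix(intensities$fluor_bg, nx, ny)
  labels <- matrix(0L, nx, ny)
  truth_t$border_clipped <- FALSE

  for (i in seq_len(nrow(truth_t))) {
    st <- truth_t[i, ]
    px <- capsule_pixels(st, nx, ny, pixel_size_um)
    truth_t$border_clipped[i] <- px$clipped
    if (length(px$wall) == 0 && length(px$lumen) == 0) next
    labels[px$wall] <- as.integer(st$structure_id)
    labels[px$lumen] <- as.integer(st$structure_id)
    if (blur_sigma_px[i] > 0) {
      bf <- composite_blurred(bf, px, blur_sigma_px[i], intensities)
    } else {
      bf[px$wall] <- intensities$bf_fg
      bf[px$lumen] <- intensities$bf_bg
    }
    if (st$class %in% c("spheroid", "tubule")) {
      if (isTRUE(st$converted)) {
        g <- px$wall[stats::runif(length(px$wall)) < mosaic_green_fraction]
        r <- setdiff(px$wall, g)
      } else {
        g <- integer(0); r <- px$wall
      }
      red[r] <- intensities$fluor_fg
      green[g] <- intensities$fluor_fg
    }
  }
  if (noise_sd > 0) {
    n <- nx * ny
    bf <- bf + stats::rnorm(n, 0, noise_sd)
    red <- red + stats::rnorm(n, 0, noise_sd)
    green <- green + stats::rnorm(n, 0, noise_sd)
  }
  clamp <- function(m) {
    m[m < 0] <- 0
    m[m > intensities$max_intensity] <- intensities$max_intensity
    m
  }
  structure(list(brightfield = clamp(bf), red = clamp(red),
                 green = clamp(green), labels = labels,
                 pixel_size_um = pixel_size_um,
                 timepoint_h = if ("timepoint_h" %in% names(truth_t))
                   truth_t$timepoint_h[1] else NA_real_,
                 truth = truth_t),
            class = "field_image")
}

# Linear pixel indices (in an nx-by-ny matrix) of a structure's wall and
# lumen, via distance to the capsule centreline segment. Returns whether the
# capsule envelope extends beyond the field.
capsule_pixels <- function(st, nx, ny, pixel_size_um) {
  w <- st$width_um; L <- st$length_um; lf <- st$lumen_fraction
  th <- st$orientation_rad
  cx <- st$cx_um; cy <- st$cy_um
  h <- (L - w) / 2                     # centreline half-length
  r_out <- w / 2
  r_in <- lf * w / 2
  ux <- cos(th); uy <- sin(th)
  # pixel window covering the capsule envelope
  ext <- h + r_out
  i0 <- max(1L, floor((cx - ext) / pixel_size_um))
  i1 <- min(nx, ceiling((cx + ext) / pixel_size_um))
  j0 <- max(1L, floor((cy - ext) / pixel_size_um))
  j1 <- min(ny, ceiling((cy + ext) / pixel_size_um))
  clipped <- (cx - ext < 0) || (cx + ext > nx * pixel_size_um) ||
             (cy - ext < 0) || (cy + ext > ny * pixel_size_um)
  if (i1 < i0 || j1 < j0)
    return(list(wall = integer(0), lumen = integer(0), clipped = clipped))
  is <- i0:i1; js <- j0:j1
  pxx <- (is - 0.5) * pixel_size_um - cx
  pyy <- (js - 0.5) * pixel_size_um - cy
  X <- matrix(pxx, length(is), length(js))
  Y <- matrix(pyy, length(is), length(js), byrow = TRUE)
  t <- pmin(pmax(X * ux + Y * uy, -h), h)
  d2 <- (X - t * ux)^2 + (Y - t * uy)^2
  wall <- d2 <= r_out^2 & d2 > r_in^2
  lumen <- if (r_in > 0) d2 <= r_in^2 else matrix(FALSE, length(is), length(js))
  idx <- function(mask) {
    sub <- which(mask, arr.ind = TRUE)
    if (nrow(sub) == 0) return(integer(0))
    (js[sub[, 2]] - 1L) * nx + is[sub[, 1]]
  }
  list(wall = idx(wall), lumen = idx(lumen), clipped = clipped)
}

# Blur one structure's bright-field contribution and max-composite it.
composite_blurred <- function(bf, px, sigma, intensities) {
  contrib <- matrix(0, nrow(bf), ncol(bf))
  contrib[px$wall] <- intensities$bf_fg - intensities$bf_bg
  blurred <- EBImage::gblur(EBImage::Image(contrib / intensities$max_intensity),
                            sigma = sigma)
  pmax(bf, intensities$bf_bg + as.numeric(EBImage::imageData(blurred)) *
         intensities$max_intensity)
}
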