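#' Segment structures from a bright-field channel
#'
#' Otsu-thresholds the bright-field channel, labels connected foreground
#' components, and fills holes; the holes retained before filling are the
#' lumen candidates of each structure. One record is returned per component
#' with area at least `min_area_um2`. Masks are disjoint; the mask of a
#' record is the foreground (wall) pixel set, its lumen mask the enclosed
#' holes, and the filled area includes both.
#'
#' @param field a `field_image` (see [render_field()]) or a list with at
#'   least `brightfield` matrix and `pixel_size_um`.
#' @param min_area_um2 minimum filled component area retained (debris
#'   filter), default 500 um^2.
#' @return list with:
#'   * `records`: data.frame, one row per structure: `structure_id`
#'     (label number), `timepoint_h`, bounding box `width_um`/`height_um`
#'     (inclusive extents), wall `area_um2`, `filled_area_um2`,
#'     `lumen_area_um2`, `lumen_circularity` (4 pi A / P^2 of the largest
#'     lumen, NA when no lumen), centroid `cx_um`/`cy_um`,
#'     `border_clipped`, and `focus_score` (rim gradient sharpness).
#'   * `labels`: integer label matrix of filled components;
#'   * `wall`, `lumen`: logical matrices.
#' @export
segment_brightfield <- function(field, min_area_um2 = 500) {
  px <- field$pixel_size_um
  if (is.null(px) || !is.finite(px) || px <= 0)
    stop("image is uncalibrated: pixel_size_um missing or non-positive")
  bf <- field$brightfield / 65535
  img <- EBImage::Image(bf)
  none <- matrix(FALSE, nrow(bf), ncol(bf))
  empty <- list(records = empty_records(),
                labels = matrix(0L, nrow(bf), ncol(bf)),
                wall = none, lumen = none)
  if (stats::sd(bf) < 1e-6) return(empty)        # blank field
  thr <- EBImage::otsu(img, range = c(0, 1))
  bin <- bf > thr
  if (!any(bin)) return(empty)
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bin))) > 0
  labf <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(filled)))
  holes <- filled & !bin
  grad <- gradient_magnitude(bf)
  rim <- bin & !EBImage::imageData(EBImage::erode(
    EBImage::Image(bin), EBImage::makeBrush(3, shape = "box"))) > 0
  bg_level <- stats::median(bf[!filled])
  nlab <- max(labf)
  rows <- vector("list", nlab)
  keep <- logical(nlab)
  px_area <- px^2
  nx <- nrow(bf); ny <- ncol(bf)
  for (l in seq_len(nlab)) {
    comp <- labf == l
    filled_n <- sum(comp)
    if (filled_n * px_area < min_area_um2) { labf[comp] <- 0L; next }
    keep[l] <- TRUE
    wall_mask <- comp & bin
    lumen_mask <- comp & holes
    sub <- which(comp, arr.ind = TRUE)
    i_rng <- range(sub[, 1]); j_rng <- range(sub[, 2])
    wall_idx <- which(wall_mask)
    lum <- lumen_features(lumen_mask, px)
    rim_idx <- which(rim & comp)
    contrast <- mean(bf[wall_idx]) - bg_level
    focus <- if (length(rim_idx) && contrast > 0)
      mean(grad[rim_idx]) / contrast else 0
    rows[[l]] <- data.frame(
      structure_id = l,
      timepoint_h = if (!is.null(field$timepoint_h)) field$timepoint_h else NA_real_,
      width_um = diff(i_rng + c(0, 1)) * px,
      height_um = diff(j_rng + c(0, 1)) * px,
      area_um2 = length(wall_idx) * px_area,
      filled_area_um2 = filled_n * px_area,
      lumen_area_um2 = lum$area_um2,
      lumen_circularity = lum$circularity,
      cx_um = (mean(sub[, 1]) - 0.5) * px,
      cy_um = (mean(sub[, 2]) - 0.5) * px,
      border_clipped = i_rng[1] == 1 || j_rng[1] == 1 ||
        i_rng[2] == nx || j_rng[2] == ny,
      focus_score = focus,
      stringsAsFactors = FALSE
    )
  }
  records <- if (any(keep)) do.call(rbind, rows[keep]) else empty_records()
  rownames(records) <- NULL
  list(records = records, labels = labf, wall = bin & labf > 0,
       lumen = holes & labf > 0)
}

empty_records <- function() {
  data.frame(structure_id = integer(0), timepoint_h = numeric(0),
             width_um = numeric(0), height_um = numeric(0),
             area_um2 = numeric(0), filled_area_um2 = numeric(0),
             lumen_area_um2 = numeric(0), lumen_circularity = numeric(0),
             cx_um = numeric(0), cy_um = numeric(0),
             border_clipped = logical(0), focus_score = numeric(0),
             stringsAsFactors = FALSE)
}

# area and circularity (4 pi A / P^2) of the largest connected lumen
lumen_features <- function(lumen_mask, px) {
  if (!any(lumen_mask)) return(list(area_um2 = 0, circularity = NA_real_))
  lab <- EBImage::bwlabel(EBImage::Image(lumen_mask))
  ft <- EBImage::computeFeatures.shape(lab)
  total <- sum(ft[, "s.area"])
  big <- which.max(ft[, "s.area"])
  per <- ft[big, "s.perimeter"]
  circ <- if (per > 0) 4 * pi * ft[big, "s.area"] / per^2 else NA_real_
  list(area_um2 = total * px^2, circularity = min(circ, 1.1))
}

gradient_magnitude <- function(m) {
  gx <- m * 0; gy <- m * 0
  nx <- nrow(m); ny <- ncol(m)
  gx[2:(nx - 1), ] <- (m[3:nx, ] - m[1:(nx - 2), ]) / 2
  gy[, 2:(ny - 1)] <- (m[, 3:ny] - m[, 1:(ny - 2)]) / 2
  sqrt(gx^2 + gy^2)
}

#' Apply the study's exclusion rules
#'
#' Structures not fully within the field of view (mask touching the image
#' border) are excluded with reason `"boundary"`; structures whose rim
#' sharpness (mean gradient magnitude on the mask rim, normalised by the
#' structure/background contrast) falls below `focus_threshold` are excluded
#' with reason `"focus"` (out of the plane of focus). All other records are
#' kept; kept and excluded partition the input.
#'
#' @param records record table from [segment_brightfield()].
#' @param focus_threshold minimum normalised rim sharpness; the default 0.2
#'   is calibrated so renders defocused with Gaussian sigma >= 3 px are
#'   excluded while sharp renders are kept.
#' @return list with `kept` and `excluded` data.frames; `excluded` carries a
#'   `reason` column.
#' @export
apply_exclusions <- function(records, focus_threshold = 0.2) {
  if (nrow(records) == 0)
    return(list(kept = records, excluded = cbind(records, reason = character(0))))
  reason <- rep(NA_character_, nrow(records))
  reason[records$focus_score < focus_threshold] <- "focus"
  reason[records$border_clipped] <- "boundary"   # boundary takes precedence
  excl <- !is.na(reason)
  excluded <- records[excl, , drop = FALSE]
  excluded$reason <- reason[excl]
  list(kept = records[!excl, , drop = FALSE], excluded = excluded)
}

#' Region statistics of a pixel mask
#'
#' Axis-aligned bounding-box extents and pixel-count area of a logical mask,
#' in calibrated units. Pure function of the mask: bounding boxes are
#' half-open in pixel indices and reported dimensions are inclusive in
#' micrometres (a single pixel measures `pixel_size_um` across).
#'
#' @param mask logical matrix (x by y).
#' @param pixel_size_um micrometres per pixel.
#' @return list `width_um`, `height_um`, `area_um2`.
#' @export
region_stats <- function(mask, pixel_size_um) {
  if (!any(mask)) stop("empty mask")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  sub <- which(mask, arr.ind = TRUE)
  list(width_um = diff(range(sub[, 1]) + c(0, 1)) * pixel_size_um,
       height_um = diff(range(sub[, 2]) + c(0, 1)) * pixel_size_um,
       area_um2 = nrow(sub) * pixel_size_um^2)
}

#' Match segmented records to ground-truth structures
#'
#' For synthetic fields, maps each segmented component to the generator
#' structure whose ground-truth label mask it overlaps most (majority vote
#' over the filled component).
#'
#' @param seg segmentation result from [segment_brightfield()].
#' @param field the rendered `field_image` (provides ground-truth `labels`).
#' @return `seg$records` with a `true_id` column (NA when a component
#'   overlaps no truth pixels).
#' @export
match_to_truth <- function(seg, field) {
  if (is.null(field$labels)) stop("field has no ground-truth labels")
  records <- seg$records
  records$true_id <- NA_integer_
  for (i in seq_len(nrow(records))) {
    idx <- which(seg$labels == records$structure_id[i])
    overlap <- field$labels[idx]
    overlap <- overlap[overlap > 0]
    if (length(overlap))
      records$true_id[i] <- as.integer(names(which.max(table(overlap))))
  }
  records
}
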