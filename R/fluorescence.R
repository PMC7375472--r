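#' Background-based intensity threshold for reporter channels
#'
#' Estimates the per-channel positivity threshold as mean + 2 sd of the
#' background intensity, computed outside all structure masks. The exact
#' rule used by interactive colour pixel counters is unpublished; this rule
#' is declared and configurable.
#'
#' @param channel intensity matrix.
#' @param labels integer label matrix (0 = background), same shape.
#' @param k number of background standard deviations above the mean.
#' @return numeric threshold in intensity units.
#' @export
background_threshold <- function(channel, labels, k = 2) {
  bg <- channel[labels == 0]
  if (!length(bg)) stop("no background pixels outside masks")
  mean(bg) + k * stats::sd(bg)
}

#' Colour pixel counts and conversion call for one structure
#'
#' Counts mask pixels whose red (green) intensity exceeds the threshold; a
#' pixel may count in both channels (membranes overlap, so double-positive
#' pixels are counted in both; set `winner_takes_all = TRUE` to assign each
#' pixel only to its brighter channel). The green fraction
#' `green / (green + red)` summarises conversion; a structure is called
#' converted when the fraction reaches `call_cutoff`.
#'
#' @param mask_idx integer (linear) pixel indices of the structure mask.
#' @param red,green channel intensity matrices.
#' @param threshold intensity threshold (see [background_threshold()]).
#' @param call_cutoff green-fraction cutoff for the conversion call.
#' @param winner_takes_all count double-positive pixels only in the brighter
#'   channel.
#' @param min_signal_fraction minimum fraction of mask pixels that must be
#'   positive in either channel for the structure to count as expressing the
#'   reporter; below it (e.g. reporter-negative prestructures, where only
#'   isolated noise pixels cross the threshold) the structure is flagged
#'   `no_signal`, the fraction reported as 0 and no conversion called.
#' @return one-row data.frame: `red_pixels`, `green_pixels`,
#'   `green_fraction`, `no_signal` (TRUE when both counts are zero, in which
#'   case the fraction is reported as 0), `converted_call`,
#'   `threshold_used`.
#' @export
count_color_pixels <- function(mask_idx, red, green, threshold,
                               call_cutoff = 0.5, winner_takes_all = FALSE,
                               min_signal_fraction = 0.1) {
  if (length(mask_idx) == 0) stop("empty mask")
  if (any(mask_idx < 1 | mask_idx > length(red)))
    stop("mask extends outside the image")
  r <- red[mask_idx] > threshold
  g <- green[mask_idx] > threshold
  if (winner_takes_all) {
    brighter_red <- red[mask_idx] >= green[mask_idx]
    r <- r & brighter_red
    g <- g & !brighter_red
  }
  nr <- sum(r); ng <- sum(g)
  no_signal <- (nr + ng) < min_signal_fraction * length(mask_idx)
  gf <- if (no_signal) 0 else ng / (ng + nr)
  data.frame(red_pixels = nr, green_pixels = ng, green_fraction = gf,
             no_signal = no_signal,
             converted_call = !no_signal && gf >= call_cutoff,
             threshold_used = threshold)
}

#' Quantify reporter conversion for every structure in a field
#'
#' @param seg segmentation result from [segment_brightfield()].
#' @param field the `field_image` the segmentation came from.
#' @param call_cutoff,winner_takes_all see [count_color_pixels()].
#' @return `seg$records` with the conversion measure columns appended.
#' @export
quantify_conversion <- function(seg, field, call_cutoff = 0.5,
                                winner_takes_all = FALSE) {
  records <- seg$records
  if (nrow(records) == 0) return(records)
  thr_r <- background_threshold(field$red, seg$labels)
  thr_g <- background_threshold(field$green, seg$labels)
  thr <- max(thr_r, thr_g)
  meas <- do.call(rbind, lapply(records$structure_id, function(l) {
    idx <- which(seg$labels == l & seg$wall)
    count_color_pixels(idx, field$red, field$green, thr,
                       call_cutoff = call_cutoff,
                       winner_takes_all = winner_takes_all)
  }))
  cbind(records, meas)
}

#' Per-arm conversion summary of tracked differentiated structures
#'
#' Fraction of differentiated structures (spheroid or tubule calls) called
#' converted at one or more post-induction timepoints, per treatment arm.
#'
#' @param records classified, conversion-quantified record table with `arm`,
#'   `track_id`, `timepoint_h`, `label` and `converted_call` columns.
#' @param induction_time_h induction time (h).
#' @return data.frame per arm: `n_differentiated`, `n_converted`,
#'   `converted_fraction`, `flagged` (TRUE when an arm has no differentiated
#'   structures, in which case fractions are NA).
#' @export
conversion_summary <- function(records, induction_time_h = 0) {
  post <- records[records$timepoint_h > induction_time_h, , drop = FALSE]
  out <- lapply(split(post, post$arm), function(g) {
    diff_g <- g[g$label %in% c("spheroid", "tubule"), , drop = FALSE]
    if (nrow(diff_g) == 0)
      return(data.frame(arm = g$arm[1], n_differentiated = 0L,
                        n_converted = 0L, converted_fraction = NA_real_,
                        flagged = TRUE))
    conv <- vapply(split(diff_g$converted_call, diff_g$track_id), any,
                   logical(1))
    data.frame(arm = g$arm[1], n_differentiated = length(conv),
               n_converted = sum(conv),
               converted_fraction = mean(conv), flagged = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
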