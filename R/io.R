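#' View a simulated truth table as measurement-style records
#'
#' Maps analytic ground truth onto the record schema used by the
#' measurement-side modules (axis-aligned bbox extents as
#' `width_um`/`height_um`, `track_id` = generator structure id), so tracking
#' and statistics can be exercised directly on noise-free truth without
#' rendering and segmenting images.
#'
#' @param truth long truth table from [simulate_timecourse()].
#' @return data.frame with `structure_id`, `track_id`, `arm`,
#'   `timepoint_h`, `width_um`, `height_um`, `area_um2`, `filled_area_um2`,
#'   `cx_um`, `cy_um`, `class`, `converted`.
#' @export
truth_as_records <- function(truth) {
  data.frame(structure_id = truth$structure_id,
             track_id = truth$structure_id, arm = truth$arm,
             timepoint_h = truth$timepoint_h,
             width_um = truth$bbox_w_um, height_um = truth$bbox_h_um,
             area_um2 = truth$area_um2,
             filled_area_um2 = truth$filled_area_um2,
             cx_um = truth$cx_um, cy_um = truth$cy_um,
             class = truth$class, converted = truth$converted,
             stringsAsFactors = FALSE)
}

#' Write a field image as a multi-page TIFF
#'
#' Pages are bright-field, red, green (16-bit). Requires the `tiff` package.
#'
#' @param field a `field_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF output")
  pages <- lapply(list(field$brightfield, field$red, field$green),
                  function(m) t(m) / 65535)   # row-major image convention
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_field_tiff()]
#'
#' @param path TIFF path.
#' @param pixel_size_um calibration to attach (um per pixel).
#' @param timepoint_h acquisition time to attach (h).
#' @return a `field_image` (without labels or truth).
#' @export
read_field_tiff <- function(path, pixel_size_um, timepoint_h = NA_real_) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF input")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 3) stop("expected 3 pages (brightfield, red, green)")
  un <- function(p) t(p) * 65535
  structure(list(brightfield = un(pages[[1]]), red = un(pages[[2]]),
                 green = un(pages[[3]]), labels = NULL,
                 pixel_size_um = pixel_size_um, timepoint_h = timepoint_h,
                 truth = NULL),
            class = "field_image")
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
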