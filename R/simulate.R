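#' Default shape priors for the synthetic tubuloid generator
#'
#' Per-class sampling ranges for structure geometry, chosen to emulate the
#' morphologies seen in primary-kidney tubuloid cultures: globular lumen-less
#' prestructures, near-circular spheroids with a clear circular lumen, and
#' elongated tubules with a slit-like lumen roughly 50 um in diameter.
#' Orientations are kept close to the image axes (uniform on
#' `orientation_range` radians) because region statistics use axis-aligned
#' bounding boxes, mirroring drawn-ROI measurements.
#'
#' @return nested list of per-class ranges: `width_um`, `aspect`
#'   (length/width), `lumen_fraction`, plus shared `orientation_range`.
#' @export
default_shape_priors <- function() {
  list(
    prestructure = list(width_um = c(50, 110), aspect = c(1.0, 1.3),
                        lumen_fraction = c(0, 0)),
    spheroid     = list(width_um = c(60, 120), aspect = c(1.0, 1.15),
                        lumen_fraction = c(0.40, 0.65)),
    tubule       = list(width_um = c(35, 60),  aspect = c(2.5, 3.2),
                        lumen_fraction = c(0.30, 0.50)),
    orientation_range = c(-0.05, 0.05)
  )
}

structure_classes <- function() c("prestructure", "spheroid", "tubule")

#' Sample one synthetic structure of a given class
#'
#' Draws geometry from the class prior and returns both the shape parameters
#' and the matching analytic ground truth (areas, axis-aligned bounding box,
#' true spherical agreement). Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param kind one of `"prestructure"`, `"spheroid"`, `"tubule"`.
#' @param priors prior list as from [default_shape_priors()].
#' @param centroid_um numeric length-2 position of the structure centre in
#'   field coordinates (um).
#' @param width_um,length_um,lumen_fraction,orientation_rad optional forced
#'   values overriding the prior draw (used for fixtures and oracles).
#' @return one-row data.frame of ground truth: class, geometry, analytic
#'   wall/filled/lumen areas, bbox dimensions and true agreement score.
#' @export
generate_structure <- function(kind, priors = default_shape_priors(),
                               centroid_um = c(0, 0),
                               width_um = NULL, length_um = NULL,
                               lumen_fraction = NULL, orientation_rad = NULL) {
  if (!kind %in% structure_classes())
    stop("unknown structure class: ", kind)
  pr <- priors[[kind]]
  w  <- if (is.null(width_um)) stats::runif(1, pr$width_um[1], pr$width_um[2]) else width_um
  if (is.null(length_um)) {
    asp <- stats::runif(1, pr$aspect[1], pr$aspect[2])
    L <- asp * w
  } else L <- length_um
  lf <- if (is.null(lumen_fraction))
    stats::runif(1, pr$lumen_fraction[1], pr$lumen_fraction[2]) else lumen_fraction
  th <- if (is.null(orientation_rad))
    stats::runif(1, priors$orientation_range[1], priors$orientation_range[2]) else orientation_rad
  validate_shape(kind, w, L, lf)
  structure_truth_row(kind, w, L, lf, th, centroid_um[1], centroid_um[2])
}

validate_shape <- function(kind, width_um, length_um, lumen_fraction) {
  check_capsule_dims(width_um, length_um)
  if (lumen_fraction < 0 || lumen_fraction >= 0.9)
    stop("lumen_fraction must be in [0, 0.9)")
  aspect <- length_um / width_um
  if (kind == "prestructure" && lumen_fraction != 0)
    stop("prestructures have no lumen (lumen_fraction must be 0)")
  if (kind == "spheroid" && aspect > 1.2 + 1e-9)
    stop("spheroid aspect ratio must be <= 1.2")
  if (kind == "tubule") {
    if (aspect < 2) stop("tubule aspect ratio must be >= 2")
    if (width_um < 30 || width_um > 80)
      stop("tubule width must be in [30, 80] um")
  }
  invisible(TRUE)
}

structure_truth_row <- function(kind, w, L, lf, th, cx, cy) {
  # vectorised over structures
  bb <- capsule_bbox(w, L, th)
  filled <- capsule_filled_area(w, L)
  sc <- spherical_agreement(bb$width_um, bb$height_um, filled)
  data.frame(
    class = kind, width_um = w, length_um = L, lumen_fraction = lf,
    orientation_rad = th, cx_um = cx, cy_um = cy,
    area_um2 = capsule_area(w, L, lf), filled_area_um2 = filled,
    lumen_area_um2 = capsule_lumen_area(w, L, lf),
    bbox_w_um = bb$width_um, bbox_h_um = bb$height_um,
    agreement_true = sc$agreement,
    stringsAsFactors = FALSE
  )
}

#' Generate a field's worth of structures with non-overlapping placement
#'
#' @param composition named integer vector, e.g.
#'   `c(prestructure = 5, spheroid = 10, tubule = 10)`.
#' @param field_um numeric length-2 field extent (x, y) in micrometres.
#' @param priors see [default_shape_priors()].
#' @param margin_um minimum clearance between structure envelopes and to the
#'   field border; structures are placed fully interior by default.
#' @param max_tries rejection-sampling attempts per structure.
#' @return data.frame of ground truth rows (one per structure) with
#'   `structure_id` and `border_clipped` columns.
#' @export
generate_field_structures <- function(composition,
                                      field_um = c(2200, 2200),
                                      priors = default_shape_priors(),
                                      margin_um = 25, max_tries = 500) {
  stopifnot(length(composition) > 0, !is.null(names(composition)))
  bad <- setdiff(names(composition), structure_classes())
  if (length(bad)) stop("unknown structure class: ", paste(bad, collapse = ", "))
  kinds <- rep(names(composition), times = composition)
  rows <- vector("list", length(kinds))
  placed_c <- matrix(numeric(0), ncol = 2)
  placed_r <- numeric(0)
  for (i in seq_along(kinds)) {
    tr <- generate_structure(kinds[i], priors)
    rad <- tr$length_um / 2           # envelope radius
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, rad + margin_um, field_um[1] - rad - margin_um)
      cy <- stats::runif(1, rad + margin_um, field_um[2] - rad - margin_um)
      if (nrow(placed_c) == 0 ||
          all(sqrt((placed_c[, 1] - cx)^2 + (placed_c[, 2] - cy)^2) >
              placed_r + rad + margin_um)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place structure ", i, " without overlap; ",
                  "reduce counts or enlarge field_um")
    tr$cx_um <- cx; tr$cy_um <- cy
    placed_c <- rbind(placed_c, c(cx, cy))
    placed_r <- c(placed_r, rad)
    rows[[i]] <- tr
  }
  out <- do.call(rbind, rows)
  out$structure_id <- seq_len(nrow(out))
  out$border_clipped <- FALSE
  out[, c("structure_id", setdiff(names(out), "structure_id"))]
}

#' Time-course configuration for the synthetic generator
#'
#' Encodes one treatment arm of the induction experiment: imaging timepoints,
#' induction time (doxycycline or vehicle addition), the exponential
#' relaxation rate of converted structures toward circularity, conversion
#' probability and mosaicism of the red-to-green reporter switch, and
#' per-timepoint multiplicative geometric jitter. The control arm never
#' converts (`conversion_prob` forced to 0).
#'
#' @param timepoints_h strictly increasing imaging times in hours; the
#'   default images immediately before induction and at 48, 96 and 168 h.
#' @param induction_time_h time of doxycycline/DMSO addition (h); timepoints
#'   `<= induction_time_h` count as pre-induction.
#' @param arm `"doxycycline"` or `"control"`.
#' @param relaxation_rate_per_h exponential rate (per hour) at which a
#'   converted structure's elongation decays toward 1; the default 0.00625
#'   leaves 35% of the excess elongation at 168 h.
#' @param conversion_prob per-structure probability that a differentiated
#'   structure converts when induced.
#' @param mosaic_green_fraction fraction of a converted structure's reporter
#'   pixels that switch to green (mosaicism of recombination).
#' @param jitter_sd standard deviation of multiplicative log-normal noise
#'   applied independently to width and length at each timepoint.
#' @param drift_sd_um per-timepoint random-walk displacement (um) of the
#'   structure centroid; structures are embedded in gel and nearly still.
#' @return validated list of class `timecourse_config`.
#' @export
timecourse_config <- function(timepoints_h = c(0, 48, 96, 168),
                              induction_time_h = 0,
                              arm = c("doxycycline", "control"),
                              relaxation_rate_per_h = 0.00625,
                              conversion_prob = 0.8,
                              mosaic_green_fraction = 0.85,
                              jitter_sd = 0.03,
                              drift_sd_um = 4) {
  arm <- match.arg(arm)
  if (length(timepoints_h) < 2 || any(diff(timepoints_h) <= 0))
    stop("timepoints_h must be strictly increasing with >= 2 timepoints")
  if (!any(timepoints_h <= induction_time_h))
    stop("need at least one pre-induction timepoint")
  if (relaxation_rate_per_h < 0) stop("relaxation_rate_per_h must be >= 0")
  for (p in c(conversion_prob, mosaic_green_fraction))
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  if (jitter_sd < 0 || drift_sd_um < 0) stop("noise scales must be >= 0")
  if (arm == "control") conversion_prob <- 0
  structure(list(timepoints_h = timepoints_h,
                 induction_time_h = induction_time_h, arm = arm,
                 relaxation_rate_per_h = relaxation_rate_per_h,
                 conversion_prob = conversion_prob,
                 mosaic_green_fraction = mosaic_green_fraction,
                 jitter_sd = jitter_sd, drift_sd_um = drift_sd_um),
            class = "timecourse_config")
}

#' Simulate structure geometry across a treatment time course
#'
#' Fills the per-timepoint truth table. Differentiated structures (spheroids
#' and tubules) convert with probability `tc$conversion_prob`; prestructures
#' never convert (the inducible Cre is restricted to epithelial structures).
#' For a converted structure at time `t >= induction`, elongation follows
#' `E(t) = 1 + (E0 - 1) * exp(-lambda * (t - t_induction))` with width
#' preserved and length shrinking accordingly; all structures additionally
#' receive multiplicative log-normal jitter on width and length and a small
#' centroid random walk at each timepoint after the first.
#'
#' @param truth baseline ground-truth table from
#'   [generate_field_structures()] (geometry at the first timepoint).
#' @param tc a [timecourse_config()].
#' @return long-format truth data.frame: one row per structure per timepoint,
#'   with `timepoint_h`, `converted`, geometry, analytic areas, bbox and true
#'   agreement.
#' @export
simulate_timecourse <- function(truth, tc) {
  stopifnot(inherits(tc, "timecourse_config"))
  if (nrow(truth) == 0) stop("empty structure table")
  differentiated <- truth$class %in% c("spheroid", "tubule")
  converted <- differentiated & (stats::runif(nrow(truth)) < tc$conversion_prob)
  lambda <- tc$relaxation_rate_per_h
  out <- vector("list", length(tc$timepoints_h))
  cx <- truth$cx_um; cy <- truth$cy_um
  for (k in seq_along(tc$timepoints_h)) {
    t <- tc$timepoints_h[k]
    E0 <- truth$length_um / truth$width_um
    E  <- E0
    post <- t >= tc$induction_time_h
    if (post && any(converted)) {
      dt <- t - tc$induction_time_h
      E[converted] <- 1 + (E0[converted] - 1) * exp(-lambda * dt)
    }
    w <- truth$width_um
    L <- E * w
    if (tc$jitter_sd > 0 && k > 1) {
      w <- w * exp(stats::rnorm(length(w), 0, tc$jitter_sd))
      L <- L * exp(stats::rnorm(length(L), 0, tc$jitter_sd))
      L <- pmax(L, w)
    }
    if (tc$drift_sd_um > 0 && k > 1) {
      cx <- cx + stats::rnorm(length(cx), 0, tc$drift_sd_um)
      cy <- cy + stats::rnorm(length(cy), 0, tc$drift_sd_um)
    }
    tab <- structure_truth_row(truth$class, w, L, truth$lumen_fraction,
                               truth$orientation_rad, cx, cy)
    tab$structure_id <- truth$structure_id
    tab$timepoint_h <- t
    tab$converted <- converted
    tab$arm <- tc$arm
    out[[k]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("structure_id", "timepoint_h", "arm", "converted",
          setdiff(names(res), c("structure_id", "timepoint_h", "arm",
                                "converted")))]
}

#' Truth-level two-arm tracked experiment
#'
#' Simulates the doxycycline and control arms of the tracked-structure
#' experiment at the ground-truth level (no rendering or segmentation):
#' geometry over the time course mapped onto the measurement record schema,
#' with arm-qualified track ids. This is the fast path used for seed sweeps
#' of the statistical layer; the imaging path ([run_pipeline()]) measures
#' the same quantities from rendered pixels.
#'
#' @param composition named per-arm structure counts.
#' @param tc_args list of overrides passed to [timecourse_config()]
#'   (besides `arm`).
#' @param field_um field extent for placement (um).
#' @return combined record table for both arms, ready for
#'   [fig5_analysis()].
#' @export
simulate_tracked_experiment <- function(composition = c(spheroid = 10,
                                                        tubule = 10),
                                        tc_args = list(),
                                        field_um = c(2200, 2200)) {
  res <- lapply(c("doxycycline", "control"), function(arm) {
    tc <- do.call(timecourse_config, c(list(arm = arm), tc_args))
    base <- generate_field_structures(composition, field_um = field_um)
    rec <- truth_as_records(simulate_timecourse(base, tc))
    rec$track_id <- paste0(arm, "_", rec$track_id)
    rec
  })
  do.call(rbind, res)
}
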