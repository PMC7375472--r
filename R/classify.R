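#' Classification thresholds
#'
#' Numeric operationalizations of the descriptive class criteria: spheroids
#' have a circular clear lumen and near-unit aspect ratio; tubules have a
#' slit-like lumen and a diameter of about 50 um; prestructures are globular
#' and lumen-less. All cutoffs are declared conventions, reported alongside
#' every classification output.
#'
#' @param lumen_fraction_min minimum lumen-to-structure area ratio for a
#'   lumen to count as present (below: prestructure).
#' @param spheroid_circularity_min minimum circularity (4 pi A / P^2) of the
#'   largest lumen for a spheroid call.
#' @param spheroid_aspect_max maximum bounding-box aspect ratio for a
#'   spheroid call.
#' @param tubule_aspect_min minimum aspect ratio for a tubule call.
#' @param tubule_diameter_um length-2 admissible band for the tubule minor
#'   dimension (um), centred on the nominal ~50 um tubule diameter.
#' @return named list of thresholds.
#' @export
classification_thresholds <- function(lumen_fraction_min = 0.05,
                                      spheroid_circularity_min = 0.6,
                                      spheroid_aspect_max = 1.5,
                                      tubule_aspect_min = 2.0,
                                      tubule_diameter_um = c(30, 80)) {
  list(lumen_fraction_min = lumen_fraction_min,
       spheroid_circularity_min = spheroid_circularity_min,
       spheroid_aspect_max = spheroid_aspect_max,
       tubule_aspect_min = tubule_aspect_min,
       tubule_diameter_um = tubule_diameter_um)
}

#' Classify segmented structures
#'
#' Deterministic first-match rule cascade on region descriptors:
#' 1. lumen area fraction below `lumen_fraction_min` -> `prestructure`;
#' 2. lumen present, largest-lumen circularity >=
#'    `spheroid_circularity_min` and aspect ratio <= `spheroid_aspect_max`
#'    -> `spheroid`;
#' 3. lumen present, aspect ratio >= `tubule_aspect_min` and minor bounding
#'    box dimension within `tubule_diameter_um` -> `tubule`;
#' 4. otherwise `ambiguous` (explicit reject class; the descriptive scheme
#'    had none, but a rule-based classifier needs one to avoid silent
#'    miscalls).
#'
#' @param records record table from [segment_brightfield()] (must contain
#'   `width_um`, `height_um`, `area_um2`, `lumen_area_um2`,
#'   `lumen_circularity`).
#' @param thresholds see [classification_thresholds()].
#' @return the input with columns `aspect_ratio`, `lumen_area_fraction`,
#'   `min_dimension_um`, `label` and `rule_fired` appended.
#' @export
classify_structures <- function(records,
                                thresholds = classification_thresholds()) {
  req <- c("width_um", "height_um", "area_um2", "lumen_area_um2",
           "lumen_circularity")
  if (!all(req %in% names(records)))
    stop("records lack lumen/region descriptors; run segment_brightfield first")
  th <- thresholds
  r <- records
  r$aspect_ratio <- pmax(r$width_um, r$height_um) /
    pmin(r$width_um, r$height_um)
  r$lumen_area_fraction <- ifelse(r$area_um2 > 0,
                                  r$lumen_area_um2 / r$area_um2, 0)
  r$min_dimension_um <- pmin(r$width_um, r$height_um)
  n <- nrow(r)
  label <- rep("ambiguous", n)
  rule <- rep("fallthrough", n)
  has_lumen <- r$lumen_area_fraction >= th$lumen_fraction_min
  pre <- !has_lumen
  label[pre] <- "prestructure"; rule[pre] <- "no_lumen"
  sph <- !pre & !is.na(r$lumen_circularity) &
    r$lumen_circularity >= th$spheroid_circularity_min &
    r$aspect_ratio <= th$spheroid_aspect_max
  label[sph] <- "spheroid"; rule[sph] <- "circular_lumen"
  tub <- !pre & !sph & r$aspect_ratio >= th$tubule_aspect_min &
    r$min_dimension_um >= th$tubule_diameter_um[1] &
    r$min_dimension_um <= th$tubule_diameter_um[2]
  label[tub] <- "tubule"; rule[tub] <- "slit_lumen"
  r$label <- label
  r$rule_fired <- rule
  attr(r, "thresholds") <- th
  r
}

#' Per-replicate class composition table
#'
#' Counts and fractions per class per replicate, with the derived
#' differentiated fraction (spheroids + tubules) and tubule-of-total
#' fraction used in population comparisons.
#'
#' @param classified output of [classify_structures()].
#' @param replicate optional vector (length `nrow(classified)`) of
#'   replicate/field identifiers; a single replicate is assumed if missing.
#' @return data.frame, one row per replicate: per-class counts `n_*`,
#'   `n_total`, per-class fractions `frac_*` (summing to 1),
#'   `differentiated_fraction` and `tubule_fraction`.
#' @export
classify_population <- function(classified, replicate = NULL) {
  if (nrow(classified) == 0) return(data.frame())
  rep_id <- if (is.null(replicate)) rep("rep1", nrow(classified)) else
    as.character(replicate)
  lv <- c(structure_classes(), "ambiguous")
  out <- lapply(split(classified$label, rep_id), function(lab) {
    n <- table(factor(lab, levels = lv))
    tot <- sum(n)
    row <- c(as.numeric(n), tot, as.numeric(n) / tot,
             (n[["spheroid"]] + n[["tubule"]]) / tot, n[["tubule"]] / tot)
    names(row) <- c(paste0("n_", lv), "n_total", paste0("frac_", lv),
                    "differentiated_fraction", "tubule_fraction")
    row
  })
  res <- as.data.frame(do.call(rbind, out))
  res$replicate <- names(out)
  rownames(res) <- NULL
  res[, c("replicate", setdiff(names(res), "replicate"))]
}
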