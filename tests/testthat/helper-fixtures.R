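# Shared fixtures: small synthetic fields built in code at test time.

# one forced-geometry structure as a truth table row ready for rendering
truth_row <- function(kind = "spheroid", width = 100, length = 100,
                      lumen = 0, theta = 0, cx = 150, cy = 150,
                      id = 1L, converted = FALSE) {
  tr <- generate_structure(kind, width_um = width, length_um = length,
                           lumen_fraction = lumen, orientation_rad = theta,
                           centroid_um = c(cx, cy))
  tr$structure_id <- id
  tr$converted <- converted
  tr$timepoint_h <- 0
  tr
}

# render a single structure in its own small field
render_single <- function(tr, field = c(300, 300), px = 1, noise = 0, ...) {
  render_field(tr, field_um = field, pixel_size_um = px, noise_sd = noise,
               ...)
}

# minimal record table for tracking tests
point_records <- function(t, ids, x, y) {
  data.frame(structure_id = ids, timepoint_h = t, cx_um = x, cy_um = y)
}
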