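test_that("capsule areas match the analytic formula", {
  # tubule-sized capsule, no lumen: w*(L-w) + pi*(w/2)^2
  expect_equal(capsule_area(50, 250), 50 * 200 + pi * 25^2, tolerance = 1e-12)
  expect_equal(capsule_area(50, 250), 11963.50, tolerance = 1e-6)
  # degenerate capsule (L = w) is a disk
  expect_equal(capsule_filled_area(100, 100), pi * 50^2)
  # lumen is the inward-offset capsule
  expect_equal(capsule_lumen_area(50, 150, 0.4),
               20 * 100 + pi * 10^2)
  expect_equal(capsule_area(50, 150, 0.4),
               capsule_filled_area(50, 150) - capsule_lumen_area(50, 150, 0.4))
  expect_error(capsule_area(-5, 10), "positive")
  expect_error(capsule_area(50, 40), "length_um")
})

test_that("rotated capsule bounding box has closed-form extents", {
  bb <- capsule_bbox(50, 250, 0)
  expect_equal(bb$width_um, 250)
  expect_equal(bb$height_um, 50)
  bb45 <- capsule_bbox(50, 250, pi / 4)
  expect_equal(bb45$width_um, 200 / sqrt(2) + 50)
  expect_equal(bb45$height_um, bb45$width_um)
})

test_that("generated structures satisfy their class invariants", {
  set.seed(11)
  for (rep in 1:40) for (kind in c("prestructure", "spheroid", "tubule")) {
    tr <- generate_structure(kind)
    expect_gte(tr$length_um, tr$width_um)
    expect_gt(tr$width_um, 0)
    expect_true(tr$lumen_fraction >= 0 && tr$lumen_fraction < 0.9)
    aspect <- tr$length_um / tr$width_um
    if (kind == "prestructure") expect_identical(tr$lumen_fraction, 0)
    if (kind == "spheroid") expect_lte(aspect, 1.2)
    if (kind == "tubule") {
      expect_gte(aspect, 2)
      expect_true(tr$width_um >= 30 && tr$width_um <= 80)
    }
    expect_equal(tr$area_um2,
                 capsule_area(tr$width_um, tr$length_um, tr$lumen_fraction))
  }
  expect_error(generate_structure("organoid"), "unknown structure class")
})

test_that("forced degenerate spheroid is a disk with correct truth", {
  tr <- generate_structure("spheroid", width_um = 100, length_um = 100,
                           lumen_fraction = 0.6, orientation_rad = 0)
  expect_equal(tr$length_um / tr$width_um, 1)
  expect_equal(tr$bbox_w_um, 100)
  expect_equal(tr$filled_area_um2, pi * 50^2)
  expect_equal(tr$agreement_true, 1)   # disk sits at the spheroid endpoint
})

test_that("elongation relaxes with the closed-form exponential", {
  base <- generate_structure("tubule", width_um = 40, length_um = 200,
                             lumen_fraction = 0.4, orientation_rad = 0,
                             centroid_um = c(500, 500))
  base$structure_id <- 1L
  # E0 = 5; lambda chosen so exp(-lambda*168) = 0.2 -> E(168) = 1.8
  lam <- log(5) / 168
  tc <- timecourse_config(arm = "doxycycline", relaxation_rate_per_h = lam,
                          conversion_prob = 1, jitter_sd = 0, drift_sd_um = 0)
  tru <- simulate_timecourse(base, tc)
  E <- tru$length_um / tru$width_um
  expect_equal(E[tru$timepoint_h == 0], 5)       # induction instant: E0
  expect_equal(E[tru$timepoint_h == 168], 1.8, tolerance = 1e-12)
  expect_equal(tru$width_um, rep(40, 4))          # width preserved
  # area follows the capsule formula at the relaxed length
  r168 <- tru[tru$timepoint_h == 168, ]
  expect_equal(r168$area_um2,
               capsule_area(r168$width_um, r168$length_um, 0.4))
})

test_that("zero relaxation and zero jitter leave geometry exactly at baseline", {
  set.seed(3)
  base <- generate_field_structures(c(spheroid = 3, tubule = 3),
                                    field_um = c(1500, 1500))
  tc <- timecourse_config(arm = "doxycycline", relaxation_rate_per_h = 0,
                          conversion_prob = 1, jitter_sd = 0, drift_sd_um = 0)
  tru <- simulate_timecourse(base, tc)
  for (t in c(48, 96, 168)) {
    tt <- tru[tru$timepoint_h == t, ]
    expect_equal(tt$length_um, base$length_um)
    expect_equal(tt$width_um, base$width_um)
    expect_equal(tt$area_um2, base$area_um2)
  }
})

test_that("control arms never convert and prestructures are immune", {
  set.seed(5)
  base <- generate_field_structures(
    c(prestructure = 4, spheroid = 4, tubule = 4), field_um = c(1800, 1800))
  ctl <- timecourse_config(arm = "control", conversion_prob = 1)
  expect_identical(ctl$conversion_prob, 0)       # forced by the arm contract
  tru_c <- simulate_timecourse(base, ctl)
  expect_false(any(tru_c$converted))
  dox <- timecourse_config(arm = "doxycycline", conversion_prob = 1)
  tru_d <- simulate_timecourse(base, dox)
  expect_false(any(tru_d$converted[tru_d$class == "prestructure"]))
  expect_true(all(tru_d$converted[tru_d$class != "prestructure"]))
})

test_that("doxycycline conversion counts follow the configured probability", {
  set.seed(9)
  props <- replicate(30, {
    base <- generate_field_structures(c(spheroid = 5, tubule = 5),
                                      field_um = c(1800, 1800))
    tru <- simulate_timecourse(base,
      timecourse_config(arm = "doxycycline", conversion_prob = 0.8))
    mean(tru$converted[tru$timepoint_h == 0])
  })
  # seed-averaged proportion vs Binomial(300, 0.8) (4 sd band)
  expect_lt(abs(mean(props) - 0.8), 4 * sqrt(0.8 * 0.2 / 300))
})

test_that("identical seeds reproduce identical truth tables", {
  gen <- function() {
    set.seed(123)
    base <- generate_field_structures(c(spheroid = 4, tubule = 4),
                                      field_um = c(1500, 1500))
    simulate_timecourse(base, timecourse_config(arm = "doxycycline"))
  }
  expect_identical(gen(), gen())
})

test_that("time-course configuration rejects invalid inputs", {
  expect_error(timecourse_config(timepoints_h = c(0, 48, 48)), "increasing")
  expect_error(timecourse_config(timepoints_h = c(24, 48), induction_time_h = 0),
               "pre-induction")
  expect_error(timecourse_config(relaxation_rate_per_h = -1), ">= 0")
  expect_error(timecourse_config(conversion_prob = 1.4), "probabilities")
  expect_error(simulate_timecourse(data.frame(), timecourse_config()),
               "empty")
})
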