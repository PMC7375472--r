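test_that("spherical-like reference areas follow both conventions", {
  ap <- spherical_like_area(50, 50, "as_printed")
  expect_equal(ap$r_um, 50)
  expect_equal(ap$spherical_like_area_um2, 2 * pi * 2500)   # 15707.96
  nm <- spherical_like_area(100, 100, "normalized")
  expect_equal(nm$r_um, 50)
  expect_equal(nm$spherical_like_area_um2, pi * 50^2)       # 7853.98
  mn <- spherical_like_area(50, 250, "normalized")
  expect_equal(mn$r_um, 25)                                 # min rule
  expect_equal(mn$spherical_like_area_um2, pi * 625)        # 1963.50
  expect_error(spherical_like_area(0, 10), "positive")
})

test_that("agreement score hits the stated endpoints", {
  # exact disk sits at 1 (spheroid endpoint)
  s <- spherical_agreement(100, 100, pi * 50^2)
  expect_identical(s$agreement, 1)
  expect_identical(s$percent_difference, 0)
  # short capsule w=50, L=75: A = 50*25 + pi*25^2 = 3213.50
  s2 <- spherical_agreement(75, 50, 50 * 25 + pi * 625)
  expect_equal(s2$percent_difference, 1250 / (pi * 625), tolerance = 1e-12)
  expect_equal(s2$agreement, 1 - 1250 / (pi * 625), tolerance = 1e-12)
  expect_equal(s2$agreement, 0.3634, tolerance = 1e-4)
  # long tubule saturates at 0 (tubule endpoint)
  s3 <- spherical_agreement(250, 50, capsule_filled_area(50, 250))
  expect_equal(s3$percent_difference, 5.093, tolerance = 1e-3)
  expect_identical(s3$agreement, 0)
})

test_that("agreement stays in [0,1] and rejects impossible geometry", {
  set.seed(31)
  for (conv in c("normalized", "as_printed")) {
    w <- runif(200, 20, 200)
    h <- runif(200, 20, 200)
    a <- runif(200, 0.1, 1) * w * h
    s <- spherical_agreement(w, h, a, convention = conv)
    expect_true(all(s$agreement >= 0 & s$agreement <= 1))
  }
  expect_error(spherical_agreement(10, 10, 200), "bounding-box")
  expect_error(spherical_agreement(10, 10, -1), "positive")
})

test_that("agreement decreases monotonically with capsule length, then clamps", {
  w <- 50
  L <- seq(50, 260, by = 2)
  S <- spherical_agreement(pmax(L, w), w, capsule_filled_area(w, L))$agreement
  expect_true(all(diff(S) <= 1e-12))
  # strictly decreasing before the clamp point L = w * (1 + pi/4)
  pre <- L < w * (1 + pi / 4)
  expect_true(all(diff(S[pre]) < 0))
  expect_true(all(S[L > w * (1 + pi / 4) + 2] == 0))
})

test_that("normalized agreement is scale invariant", {
  for (k in c(0.1, 0.5, 2, 10)) {
    s1 <- spherical_agreement(120, 60, capsule_filled_area(60, 120))
    sk <- spherical_agreement(120 * k, 60 * k,
                              capsule_filled_area(60 * k, 120 * k))
    expect_equal(sk$agreement, s1$agreement, tolerance = 1e-12)
  }
})

test_that("analytic and rasterized scores agree within 0.05", {
  set.seed(33)
  for (rep in 1:8) {
    kind <- sample(c("prestructure", "spheroid", "tubule"), 1)
    tr <- generate_structure(kind, centroid_um = c(250, 250))
    tr$structure_id <- 1L; tr$converted <- FALSE; tr$timepoint_h <- 0
    f <- render_single(tr, field = c(500, 500), px = 1)
    seg <- segment_brightfield(f)
    s_meas <- spherical_agreement(seg$records$width_um,
                                  seg$records$height_um,
                                  seg$records$filled_area_um2)
    expect_lt(abs(s_meas$agreement - tr$agreement_true), 0.05)
  }
})

test_that("before/after deltas are signed and convention-checked", {
  b <- spherical_agreement(150, 50, capsule_filled_area(50, 150))
  a <- spherical_agreement(80, 60, capsule_filled_area(60, 80))
  expect_equal(agreement_delta(b, b), 0)
  expect_gt(agreement_delta(b, a), 0)   # more cyst-like
  expect_equal(agreement_delta(a, b), -agreement_delta(b, a))
  b2 <- spherical_agreement(150, 50, capsule_filled_area(50, 150),
                            convention = "as_printed")
  expect_error(agreement_delta(b, b2), "conventions")
})

test_that("a converted tubule shows positive delta at 168 h under defaults", {
  base <- generate_structure("tubule", width_um = 50, length_um = 125,
                             lumen_fraction = 0.4, orientation_rad = 0,
                             centroid_um = c(400, 400))
  base$structure_id <- 1L
  tc <- timecourse_config(arm = "doxycycline", conversion_prob = 1,
                          jitter_sd = 0, drift_sd_um = 0)
  tru <- simulate_timecourse(base, tc)
  s0 <- tru$agreement_true[tru$timepoint_h == 0]
  s168 <- tru$agreement_true[tru$timepoint_h == 168]
  expect_gt(s168 - s0, 0)
})
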