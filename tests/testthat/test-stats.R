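test_that("paired t-test reproduces the hand-worked example", {
  r <- paired_t_test(c(1, 2, 3), c(2, 4, 5))
  expect_equal(r$statistic, 5, tolerance = 1e-12)
  expect_equal(r$df, 2)
  # closed-form t CDF for df = 2: F(t) = (1 + t/sqrt(t^2+2))/2
  expect_equal(r$p_value, 2 * (1 - (1 + 5 / sqrt(27)) / 2), tolerance = 1e-12)
  expect_equal(r$p_value, 0.0378, tolerance = 2e-3)
  expect_equal(r$mean_effect, 5 / 3)
})

test_that("paired t-test degenerates and symmetries", {
  x <- c(1, 2, 3)
  expect_error(paired_t_test(x, x), "zero variance")
  expect_error(paired_t_test(x, c(1, 2)), "length mismatch")
  fwd <- paired_t_test(x, c(2, 4, 5))
  rev <- paired_t_test(c(2, 4, 5), x)
  expect_equal(rev$statistic, -fwd$statistic)
  expect_equal(rev$p_value, fwd$p_value)
})

test_that("two-sample Student t-test reproduces the pooled-variance example", {
  r <- two_sample_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -sqrt(3) / sqrt(2), tolerance = 1e-12)  # -1.2247
  expect_equal(r$df, 4)
  sw <- two_sample_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(sw$statistic, -r$statistic)
  expect_equal(sw$p_value, r$p_value)
  expect_error(two_sample_t_test(c(1, 1), c(1, 1)), "zero pooled variance")
  one <- two_sample_t_test(c(2, 3, 4), c(1, 2, 3), tail = "one")
  expect_equal(one$p_value, r$p_value / 2)
})

test_that("t statistics and p values match the reference implementation", {
  set.seed(71)
  for (i in 1:40) {
    n <- sample(3:50, 1)
    b <- rnorm(n); a <- rnorm(n, 0.3)
    ours <- paired_t_test(b, a)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    n2 <- sample(3:50, 1)
    g1 <- rnorm(n); g2 <- rnorm(n2, 0.5)
    ours2 <- two_sample_t_test(g1, g2)
    ref2 <- t.test(g1, g2, var.equal = TRUE)
    expect_equal(ours2$statistic, unname(ref2$statistic), tolerance = 1e-10)
    expect_equal(ours2$p_value, ref2$p.value, tolerance = 1e-10)
  }
})

test_that("p is invariant to location shifts, t to positive rescaling", {
  set.seed(72)
  b <- rnorm(10); a <- rnorm(10, 0.5)
  base <- paired_t_test(b, a)
  shift <- paired_t_test(b + 7, a + 7)
  expect_equal(shift$p_value, base$p_value, tolerance = 1e-12)
  scale <- paired_t_test(3.5 * b, 3.5 * a)
  expect_equal(scale$statistic, base$statistic, tolerance = 1e-12)
})

test_that("delta-delta-Ct fold changes follow the definition", {
  expect_equal(ddct_fold_change(20, 18, 21, 19)$fold_change, 1)
  r <- ddct_fold_change(19, 18, 21, 19)   # ddCt = 1 - 2 = -1
  expect_equal(r$delta_delta_ct, -1)
  expect_equal(r$fold_change, 2)
  expect_equal(ddct_fold_change(24, 18, 23, 19)$fold_change, 0.25)
  expect_error(ddct_fold_change(NA, 1, 1, 1), "finite")
})

test_that("tracked before/after analysis tests each arm separately", {
  set.seed(73)
  rec <- simulate_tracked_experiment()
  a <- fig5_analysis(rec)
  expect_equal(nrow(a$per_track), 40)
  expect_setequal(names(a$tests), c("doxycycline", "control"))
  expect_lt(a$tests$doxycycline$p_value, 0.05)
  expect_equal(a$tests$doxycycline$df, 19)
  expect_true(all(a$per_track$before_h == 0 & a$per_track$after_h == 168))
  # converted tubules drive a positive mean shift
  expect_gt(a$tests$doxycycline$mean_effect, 0)
  expect_error(
    fig5_analysis(rec[rec$track_id %in% c("doxycycline_1", "control_1",
                                          "control_2"), ]),
    "fewer than 2")
  expect_error(fig5_analysis(data.frame(track_id = 1)), "missing columns")
})

test_that("evaluation timepoint of the tracked analysis is a parameter", {
  set.seed(74)
  rec <- simulate_tracked_experiment(tc_args = list(jitter_sd = 0,
                                                    drift_sd_um = 0))
  # jitter-free control arm has zero variance by construction; evaluate the
  # treated arm only
  rec <- rec[rec$arm == "doxycycline", ]
  a72 <- fig5_analysis(rec, eval_h = 96)
  a168 <- fig5_analysis(rec, eval_h = 168)
  expect_true(all(a72$per_track$after_h == 96))
  # relaxation is monotone: later evaluation shows a larger mean shift
  expect_gt(a168$tests$doxycycline$mean_effect,
            a72$tests$doxycycline$mean_effect)
})
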