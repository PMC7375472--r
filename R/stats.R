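#' Paired t-test on before/after measurements
#'
#' Explicit-formula paired Student t-test: for differences
#' `d = after - before`, `t = mean(d) / (sd(d) / sqrt(n))` with the n-1
#' sample standard deviation and `df = n - 1`; tail probabilities come from
#' the t distribution. The two-tailed p-value doubles the upper tail of
#' `|t|`; the one-tailed p-value is the upper tail of `t` (hypothesised
#' increase).
#'
#' @param before,after equal-length, index-aligned numeric vectors (same
#'   structure measured before and after treatment).
#' @param tail `"two"` or `"one"`.
#' @return list of class `tubulo_test`: `statistic`, `df`, `p_value`,
#'   `tail`, `n`, `mean_effect` (mean difference).
#' @examples
#' paired_t_test(c(1, 2, 3), c(2, 4, 5))   # t = 5, df = 2, p ~ 0.0378
#' @export
paired_t_test <- function(before, after, tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (length(before) != length(after)) stop("length mismatch")
  n <- length(before)
  if (n < 2) stop("need n >= 2 pairs")
  d <- after - before
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0)
    stop("degenerate input: zero variance of differences")
  t <- mean(d) / (s / sqrt(n))
  df <- n - 1
  p <- tail_p(t, df, tail)
  structure(list(statistic = t, df = df, p_value = p, tail = tail, n = n,
                 mean_effect = mean(d)), class = "tubulo_test")
}

#' Two-sample Student t-test (pooled variance)
#'
#' `t = (m1 - m2) / (s_p * sqrt(1/n1 + 1/n2))` with pooled variance
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` and
#' `df = n1 + n2 - 2` (the classical Student formulation, not Welch).
#'
#' @param group1,group2 numeric samples, each of size >= 2.
#' @inheritParams paired_t_test
#' @return list of class `tubulo_test` with `statistic`, `df`, `p_value`,
#'   `tail`, `n1`, `n2`, `mean_effect` (difference of means).
#' @export
two_sample_t_test <- function(group1, group2, tail = c("two", "one")) {
  tail <- match.arg(tail)
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  sp2 <- ((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
    (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 == 0)
    stop("degenerate input: zero pooled variance")
  t <- (mean(group1) - mean(group2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- tail_p(t, df, tail)
  structure(list(statistic = t, df = df, p_value = p, tail = tail,
                 n1 = n1, n2 = n2,
                 mean_effect = mean(group1) - mean(group2)),
            class = "tubulo_test")
}

tail_p <- function(t, df, tail) {
  if (tail == "two") 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  else stats::pt(t, df, lower.tail = FALSE)
}

#' @export
print.tubulo_test <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %d, %s-tailed p = %.4g, mean effect = %.4g\n",
              x$statistic, x$df, x$tail, x$p_value, x$mean_effect))
  invisible(x)
}

#' Relative expression fold change by the delta-delta-Ct method
#'
#' `ddCt = (Ct_target,exp - Ct_ref,exp) - (Ct_target,ctrl - Ct_ref,ctrl)`
#' and `fold_change = 2^(-ddCt)`; a ddCt of 0 is a fold change of 1.
#'
#' @param ct_target_exp,ct_ref_exp target/reference-gene Ct in the
#'   experimental group.
#' @param ct_target_ctrl,ct_ref_ctrl same in the control group.
#' @return list with `delta_delta_ct` and `fold_change`.
#' @export
ddct_fold_change <- function(ct_target_exp, ct_ref_exp,
                             ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_exp, ct_ref_exp, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_exp - ct_ref_exp) - (ct_target_ctrl - ct_ref_ctrl)
  list(delta_delta_ct = ddct, fold_change = 2^(-ddct))
}

#' Before/after spherical-agreement analysis of tracked structures
#'
#' The cyst-progression readout: for every complete track, spherical
#' agreement at the last pre-induction timepoint and at the evaluation
#' timepoint post induction, their signed change, and a per-arm paired
#' t-test on (before, after).
#'
#' @param track_records long record table with `track_id`, `arm`,
#'   `timepoint_h`, `width_um`, `height_um` and an area column.
#' @param induction_time_h induction time (h).
#' @param eval_h evaluation timepoint (h post start); the record nearest to
#'   `eval_h` among post-induction timepoints is used. Default 168.
#' @param convention morphometry convention, see [spherical_agreement()].
#' @param area_col which measured area to score; drawn-ROI-style analyses
#'   use the filled region area.
#' @return list with `per_track` (data.frame: `track_id`, `arm`,
#'   `before_h`, `after_h`, `agreement_before`, `agreement_after`, `delta`)
#'   and `tests` (named list of `tubulo_test` per arm, paired, two-tailed).
#' @export
fig5_analysis <- function(track_records, induction_time_h = 0, eval_h = 168,
                          convention = "normalized",
                          area_col = "filled_area_um2") {
  req <- c("track_id", "arm", "timepoint_h", "width_um", "height_um", area_col)
  if (!all(req %in% names(track_records)))
    stop("missing columns: ", paste(setdiff(req, names(track_records)),
                                    collapse = ", "))
  per <- lapply(split(track_records, track_records$track_id), function(g) {
    pre <- g[g$timepoint_h <= induction_time_h, , drop = FALSE]
    post <- g[g$timepoint_h > induction_time_h, , drop = FALSE]
    if (nrow(pre) == 0 || nrow(post) == 0) return(NULL)   # incomplete track
    b <- pre[which.max(pre$timepoint_h), ]
    a <- post[which.min(abs(post$timepoint_h - eval_h)), ]
    sb <- spherical_agreement(b$width_um, b$height_um, b[[area_col]],
                              convention = convention)
    sa <- spherical_agreement(a$width_um, a$height_um, a[[area_col]],
                              convention = convention)
    data.frame(track_id = g$track_id[1], arm = g$arm[1],
               before_h = b$timepoint_h, after_h = a$timepoint_h,
               agreement_before = sb$agreement,
               agreement_after = sa$agreement,
               delta = agreement_delta(sb, sa))
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0)
    stop("no complete tracks spanning induction")
  rownames(per) <- NULL
  tests <- lapply(split(per, per$arm), function(g) {
    if (nrow(g) < 2)
      stop("arm '", g$arm[1], "' has fewer than 2 complete tracks")
    paired_t_test(g$agreement_before, g$agreement_after, tail = "two")
  })
  list(per_track = per, tests = tests)
}
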