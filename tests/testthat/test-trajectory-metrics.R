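test_that("QC filter applies both rules, reports removals, and is idempotent", {
  m <- cell_matrix(matrix(rnorm(9), 3, 3), cell_time_h = c(1, 2, 3),
                   genes_detected = c(100, 300, 300),
                   mito_fraction = c(0.1, 0.3, 0.1))
  res <- qc_filter(m)
  expect_equal(nrow(res$filtered$values), 1L)
  expect_equal(res$filtered$cell_id, "cell_3")
  expect_equal(res$report$removed_by_genes_only, 1)
  expect_equal(res$report$removed_by_mito_only, 1)
  expect_equal(res$report$removed_by_both, 0)

  # vacuous thresholds are the identity
  res_all <- qc_filter(m, min_genes = 0, max_mito = 1)
  expect_equal(res_all$report$removed_total, 0)
  expect_equal(res_all$filtered$values, m$values)

  # idempotence
  twice <- qc_filter(res$filtered)
  expect_equal(twice$filtered$values, res$filtered$values)
  expect_equal(twice$report$removed_total, 0)

  # empty result warns rather than errors
  expect_warning(qc_filter(m, min_genes = 1000), "no cells")
})

test_that("pseudotime calibration reproduces its anchors and inverts exactly", {
  cal <- calibrate_pseudotime(rbind(c(16, 6.8), c(27, 10.2)))
  expect_equal(pt_apply(cal, 16), 6.8)
  expect_equal(pt_apply(cal, 27), 10.2)
  expect_equal(pt_apply(cal, 21.5), 8.5)
  hrs <- seq(0, 48, by = 0.7)
  expect_equal(pt_invert(cal, pt_apply(cal, hrs)), hrs, tolerance = 1e-9)
  expect_gt(cal$slope, 0)
  expect_error(calibrate_pseudotime(rbind(c(16, 6.8), c(16, 10.2))),
               "degenerate")
  expect_error(calibrate_pseudotime(rbind(c(16, 10.2), c(27, 6.8))),
               "increasing")
})

test_that("branch detection finds immediate splits and reports absence", {
  set.seed(30)
  # two populations separated from t = 0: detection in the first bin
  n <- 600
  t_cell <- runif(n, 0, 24)
  vals <- matrix(rnorm(n * 5, 0, 0.5), n, 5)
  vals[, 1] <- vals[, 1] + sample(c(0, 6), n, TRUE)
  m <- cell_matrix(vals, t_cell)
  est <- detect_branch_point(m, seq(0, 24, by = 4), n_boot = 0)
  expect_equal(est$branch_hour, 2)

  # single drifting population: no bifurcation to find
  vals1 <- matrix(rnorm(n * 5, 0, 0.5), n, 5)
  vals1[, 1] <- vals1[, 1] + 0.05 * t_cell
  m1 <- cell_matrix(vals1, t_cell)
  est1 <- detect_branch_point(m1, seq(0, 24, by = 4), n_boot = 0)
  expect_true(is.na(est1$branch_hour))
  expect_equal(nrow(est1$evidence), 6L)

  expect_error(detect_branch_point(m, c(0, 24)), "3 time bins")
  expect_warning(detect_branch_point(m, c(0, 0.1, 12, 24), n_boot = 0),
                 "fewer than")
})

test_that("branch detection rarely fires on branchless data", {
  false_pos <- 0L
  for (s in 1:20) {
    g <- gen_bifurcating_cells(synth_config(seed = 100 + s,
      bifurcation = list(divergence_rate = 0, n_cells = 800)))
    e <- detect_branch_point(g$cells, g$truth$time_bins, n_boot = 0)
    if (!is.na(e$branch_hour)) false_pos <- false_pos + 1L
  }
  expect_lte(false_pos, 1L)  # <= 5% of 20 datasets
})

test_that("exhaustion staging follows the time bounds and marker gate", {
  expect_equal(exhaustion_stage(10), "pre")
  expect_equal(exhaustion_stage(30, marker_level = 1), "early_suppression")
  expect_equal(exhaustion_stage(30, marker_level = -1), "pre")
  expect_equal(exhaustion_stage(80), "reprogramming")
  expect_equal(exhaustion_stage(130), "late_depletion")
  # half-open intervals and gap assignment to the earlier stage
  expect_equal(exhaustion_stage(c(24, 60, 72, 96, 120), marker_level = 1),
               c("early_suppression", "early_suppression", "reprogramming",
                 "reprogramming", "late_depletion"))
  expect_equal(exhaustion_stage(30, marker_level = 0, marker_gated = FALSE),
               "early_suppression")
})

test_that("peak fold change is the ratio of window means", {
  s <- data.frame(time_h = 0:48, value = 1)
  expect_equal(peak_fold_change(s, c(36, 48), c(0, 12)), 1.0)
  s2 <- data.frame(time_h = 0:48,
                   value = ifelse(0:48 >= 36, 7, 2))
  expect_equal(peak_fold_change(s2, c(36, 48), c(0, 12)), 3.5)
  expect_error(peak_fold_change(s, c(10, 20), c(15, 25)), "overlap")
  s0 <- data.frame(time_h = 0:48, value = c(rep(0, 13), rep(1, 36)))
  expect_error(peak_fold_change(s0, c(36, 48), c(0, 12)), "baseline")
})

test_that("lead-lag estimation recovers constructed shifts with refinement", {
  t <- seq(0, 72, by = 0.5)
  f <- function(x) exp(-((x - 30)^2) / 50) + 0.5 / (1 + exp(-(x - 15)))
  a <- data.frame(time_h = t, value = f(t))
  expect_equal(lead_lag_estimate(a, a, max_lag = 10)$lag_h, 0)

  # shift by exactly 2 grid steps of 0.5 h
  b <- data.frame(time_h = t, value = f(t - 1))
  est <- lead_lag_estimate(a, b, max_lag = 10)
  expect_equal(est$lag_h, 1.0, tolerance = 0.05)
  expect_gt(est$corr_at_peak, 0.999)

  # off-grid shift is recovered by parabolic refinement
  b2 <- data.frame(time_h = t, value = f(t - 1.3))
  expect_equal(lead_lag_estimate(a, b2, max_lag = 10)$lag_h, 1.3,
               tolerance = 0.1)

  flat <- data.frame(time_h = t, value = 1)
  expect_error(lead_lag_estimate(flat, a, max_lag = 10), "flat")
  expect_error(lead_lag_estimate(a, b, max_lag = 40), "half the span")
})

test_that("depletion rate ratio reduces to hand-computable slope ratios", {
  mk <- function(slope) data.frame(time_h = 0:4, pseudotime = slope * (0:4))
  ga <- lapply(rep(4.6, 5), mk)
  gb <- lapply(rep(2.0, 5), mk)
  rr <- depletion_rate_ratio(ga, gb, n_boot = 50, seed = 1)
  expect_equal(rr$ratio, 2.3, tolerance = 1e-9)
  same <- depletion_rate_ratio(gb, gb, n_boot = 50, seed = 1)
  expect_equal(same$ratio, 1.0)
  expect_error(depletion_rate_ratio(ga, lapply(rep(-1, 5), mk),
                                    n_boot = 10), "non-positive")
  expect_error(depletion_rate_ratio(list(data.frame(time_h = 0:1,
                                                    pseudotime = 0:1)),
                                    gb, n_boot = 10), ">= 3 points")
})

test_that("severity correlation handles exact, inverse and degenerate input", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.7)
  expect_equal(severity_correlation(x, x)$r, 1.0)
  expect_equal(severity_correlation(x, -x)$r, -1.0)
  sc <- severity_correlation(x, rev(x))
  expect_true(sc$ci[1] <= sc$r && sc$r <= sc$ci[2])
  expect_error(severity_correlation(x, rep(1, 6)), "zero variance")
  expect_error(severity_correlation(x[1:2], x[1:2]), ">= 3")
})
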