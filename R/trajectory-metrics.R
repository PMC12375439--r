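#' Cells-by-features matrix with per-cell temporal metadata
#'
#' Container for single-cell style inputs: a numeric matrix (rows = cells)
#' plus per-cell sampling hour, QC fields and an optional lineage label.
#'
#' @param values Numeric matrix, cells in rows.
#' @param cell_time_h Per-cell sampling hour.
#' @param genes_detected Per-cell detected-gene count (>= 0).
#' @param mito_fraction Per-cell mitochondrial fraction in `[0, 1]`.
#' @param lineage_label Optional per-cell categorical label.
#' @param cell_id Optional cell identifiers; defaults to `cell_1 ...`.
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(values, cell_time_h, genes_detected = NULL,
                        mito_fraction = NULL, lineage_label = NULL,
                        cell_id = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(genes_detected)) genes_detected <- rep(1000L, n)
  if (is.null(mito_fraction)) mito_fraction <- rep(0.05, n)
  if (is.null(cell_id)) cell_id <- paste0("cell_", seq_len(n))
  lens <- c(length(cell_time_h), length(genes_detected),
            length(mito_fraction), length(cell_id))
  if (any(lens != n))
    stop("cell_matrix: per-cell vectors must match nrow(values)",
         call. = FALSE)
  if (!is.null(lineage_label) && length(lineage_label) != n)
    stop("cell_matrix: lineage_label length must match nrow(values)",
         call. = FALSE)
  if (any(mito_fraction < 0 | mito_fraction > 1))
    stop("cell_matrix: mito_fraction must lie in [0, 1]", call. = FALSE)
  if (any(genes_detected < 0))
    stop("cell_matrix: genes_detected must be >= 0", call. = FALSE)
  rownames(values) <- cell_id
  structure(list(values = values,
                 cell_time_h = as.numeric(cell_time_h),
                 genes_detected = as.numeric(genes_detected),
                 mito_fraction = as.numeric(mito_fraction),
                 lineage_label = lineage_label,
                 cell_id = cell_id),
            class = "cell_matrix")
}

#' @exportS3Method base::print
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d cells x %d features, %.3g-%.3g h\n",
              nrow(x$values), ncol(x$values),
              min(x$cell_time_h), max(x$cell_time_h)))
  invisible(x)
}

#' Quality-control filter for cells
#'
#' Retains cells with at least `min_genes` detected genes AND a
#' mitochondrial fraction of at most `max_mito` (defaults: >= 200 genes,
#' <= 20% mitochondrial reads).
#'
#' @param x A [cell_matrix()].
#' @param min_genes Minimum detected-gene count. Default 200.
#' @param max_mito Maximum mitochondrial fraction. Default 0.20.
#' @return List with `filtered` (a `cell_matrix`) and `report`: counts
#'   removed by the gene rule only, the mito rule only, both rules, total
#'   removed and retained, plus an `empty` flag (warned, not an error).
#' @export
qc_filter <- function(x, min_genes = 200, max_mito = 0.20) {
  stopifnot(inherits(x, "cell_matrix"))
  fail_genes <- x$genes_detected < min_genes
  fail_mito <- x$mito_fraction > max_mito
  keep <- !fail_genes & !fail_mito
  report <- list(
    removed_by_genes_only = sum(fail_genes & !fail_mito),
    removed_by_mito_only = sum(fail_mito & !fail_genes),
    removed_by_both = sum(fail_genes & fail_mito),
    removed_total = sum(!keep),
    retained = sum(keep),
    empty = !any(keep))
  if (report$empty) warning("qc_filter: no cells pass the filter")
  filtered <- cell_matrix(
    x$values[keep, , drop = FALSE],
    x$cell_time_h[keep],
    x$genes_detected[keep],
    x$mito_fraction[keep],
    if (!is.null(x$lineage_label)) x$lineage_label[keep],
    x$cell_id[keep])
  list(filtered = filtered, report = report)
}

#' Linear calibration between wall-clock hours and pseudotime units
#'
#' Fits the unique increasing linear map through two `(hour, unit)` anchor
#' pairs, e.g. the decision-window anchors 16 h -> 6.8 units and
#' 27 h -> 10.2 units.
#'
#' @param anchors 2x2 matrix-like: rows are anchor pairs
#'   `(hour, pseudotime_unit)`; anchor hours must differ and the implied
#'   slope must be positive (order-preserving).
#' @return An object of class `calibration_map` with `slope`, `intercept`,
#'   `anchors`; use [pt_apply()] and [pt_invert()].
#' @examples
#' cal <- calibrate_pseudotime(rbind(c(16, 6.8), c(27, 10.2)))
#' pt_apply(cal, 21.5) # 8.5
#' @export
calibrate_pseudotime <- function(anchors) {
  a <- as.matrix(anchors)
  if (!all(dim(a) == c(2L, 2L)))
    stop("calibrate_pseudotime: anchors must be two (hour, unit) pairs",
         call. = FALSE)
  if (a[1L, 1L] == a[2L, 1L])
    stop("calibrate_pseudotime: degenerate anchors (equal hours)",
         call. = FALSE)
  slope <- (a[2L, 2L] - a[1L, 2L]) / (a[2L, 1L] - a[1L, 1L])
  if (slope <= 0)
    stop("calibrate_pseudotime: map must be increasing (slope > 0)",
         call. = FALSE)
  intercept <- a[1L, 2L] - slope * a[1L, 1L]
  structure(list(slope = slope, intercept = intercept, anchors = a),
            class = "calibration_map")
}

#' @rdname calibrate_pseudotime
#' @param map A `calibration_map`.
#' @param hours Hours to map to pseudotime units.
#' @export
pt_apply <- function(map, hours) {
  stopifnot(inherits(map, "calibration_map"))
  map$intercept + map$slope * hours
}

#' @rdname calibrate_pseudotime
#' @param units Pseudotime units to map back to hours.
#' @export
pt_invert <- function(map, units) {
  stopifnot(inherits(map, "calibration_map"))
  (units - map$intercept) / map$slope
}

#' Detect a fate-bifurcation time in a cell matrix
#'
#' Cells are binned by sampling hour. In each bin, the leading principal
#' direction of the bin's cells is extracted and one- and two-component
#' Gaussian mixtures are fitted to the scores (\pkg{mclust}). The
#' separation evidence per bin is `BIC(1) - BIC(2)` (classical,
#' smaller-is-better BIC, so positive values favour two components), gated
#' by a minimum standardised separation between the fitted component means
#' (`|mu_1 - mu_2| >= gate_sd x pooled within-component sd`). The branch
#' hour is the midpoint of the first bin whose gated evidence is positive
#' and remains positive in all later bins — a persistence requirement that
#' suppresses transient false splits. The confidence half-width comes from
#' a seeded bootstrap over cells (resampled within bins).
#'
#' @param x A [cell_matrix()].
#' @param time_bins Bin edges in hours (>= 4 edges, i.e. >= 3 bins).
#' @param n_boot Bootstrap resamples. Default 200; 0 skips the CI.
#' @param seed RNG seed for the bootstrap.
#' @param gate_sd Minimum mean separation in pooled-sd units. Default 1.
#' @param min_cells Per-bin cell count below which a warning is issued.
#' @return An object of class `branch_estimate`: list with `branch_hour`
#'   (`NA` if no persistent split), `ci_halfwidth`, `evidence` (data frame
#'   `bin_mid`, `bic_evidence`, `separation_sd`, `gated`), `n_boot`,
#'   `seed`.
#' @export
detect_branch_point <- function(x, time_bins, n_boot = 200, seed = 1,
                                gate_sd = 1, min_cells = 20) {
  stopifnot(inherits(x, "cell_matrix"))
  if (length(time_bins) < 4L)
    stop("detect_branch_point: need at least 3 time bins", call. = FALSE)
  counts <- table(cut(x$cell_time_h, time_bins, include.lowest = TRUE))
  if (any(counts < min_cells))
    warning("detect_branch_point: ", sum(counts < min_cells),
            " bin(s) hold fewer than ", min_cells, " cells")

  est <- branch_scan(x$values, x$cell_time_h, time_bins, gate_sd)
  ci_halfwidth <- NA_real_
  if (n_boot > 0 && !is.na(est$branch_hour)) {
    rs <- local_rng_state(as.integer(seed))
    on.exit(restore_rng_state(rs), add = TRUE)
    bins <- cut(x$cell_time_h, time_bins, include.lowest = TRUE)
    idx_by_bin <- split(seq_along(bins), bins)
    boots <- vapply(seq_len(n_boot), function(b) {
      take <- unlist(lapply(idx_by_bin, function(ii)
        if (length(ii)) sample(ii, length(ii), replace = TRUE) else ii),
        use.names = FALSE)
      branch_scan(x$values[take, , drop = FALSE], x$cell_time_h[take],
                  time_bins, gate_sd)$branch_hour
    }, numeric(1))
    boots <- boots[!is.na(boots)]
    if (length(boots) >= 2L) {
      qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
      ci_halfwidth <- (qs[2L] - qs[1L]) / 2
    }
  }
  structure(list(branch_hour = est$branch_hour, ci_halfwidth = ci_halfwidth,
                 evidence = est$evidence, n_boot = n_boot,
                 seed = as.integer(seed)),
            class = "branch_estimate")
}

# one pass of the per-bin mixture scan; returns branch_hour + evidence curve
branch_scan <- function(values, cell_time_h, time_bins, gate_sd) {
  bins <- cut(cell_time_h, time_bins, include.lowest = TRUE)
  mids <- (utils::head(time_bins, -1) + utils::tail(time_bins, -1)) / 2
  nb <- length(mids)
  ev <- data.frame(bin_mid = mids, bic_evidence = NA_real_,
                   separation_sd = NA_real_, gated = FALSE)
  for (b in seq_len(nb)) {
    sel <- which(as.integer(bins) == b)
    if (length(sel) < 10L) next
    sub <- values[sel, , drop = FALSE]
    # leading principal direction of this bin's cells
    pc <- tryCatch(stats::prcomp(sub, center = TRUE, scale. = FALSE),
                   error = function(e) NULL)
    if (is.null(pc)) next
    scores <- pc$x[, 1L]
    fit1 <- suppressWarnings(
      mclust::Mclust(scores, G = 1, modelNames = "V", verbose = FALSE))
    fit2 <- suppressWarnings(
      mclust::Mclust(scores, G = 2, modelNames = "V", verbose = FALSE))
    if (is.null(fit1) || is.null(fit2)) next
    # mclust BIC is larger-is-better; convert to classical BIC(1)-BIC(2)
    ev$bic_evidence[b] <- fit2$bic - fit1$bic
    mu <- fit2$parameters$mean
    pro <- fit2$parameters$pro
    sd_pool <- sqrt(sum(pro * fit2$parameters$variance$sigmasq))
    ev$separation_sd[b] <- abs(diff(mu)) / sd_pool
    ev$gated[b] <- ev$bic_evidence[b] > 0 && ev$separation_sd[b] >= gate_sd
  }
  # first bin from which the gated evidence stays positive to the end
  ok <- ev$gated
  branch_hour <- NA_real_
  evaluated <- !is.na(ev$bic_evidence)
  for (b in seq_len(nb)) {
    later <- evaluated & seq_len(nb) >= b
    if (ok[b] && all(ok[later])) { branch_hour <- mids[b]; break }
  }
  list(branch_hour = branch_hour, evidence = ev)
}

#' @exportS3Method base::print
print.branch_estimate <- function(x, ...) {
  if (is.na(x$branch_hour)) {
    cat("No persistent bifurcation detected.\n")
  } else {
    cat(sprintf("Estimated bifurcation at %.2f h", x$branch_hour))
    if (!is.na(x$ci_halfwidth))
      cat(sprintf(" (bootstrap half-width %.2f h, %d resamples)",
                  x$ci_halfwidth, x$n_boot))
    cat("\n")
  }
  invisible(x)
}

#' Stage a time point on the T-cell exhaustion axis
#'
#' Stages follow the three-phase exhaustion timeline: early suppression
#' (24-48 h, marker-gated), mid-phase reprogramming (72-96 h) and late
#' depletion (> 120 h). Times before 24 h are `pre`; the unnamed gaps
#' (48-72 h and 96-120 h) are assigned to the earlier stage. Intervals are
#' half-open `[lo, hi)`. The marker gate applies only to the early window:
#' below-threshold markers there report `pre` (suppression not yet
#' initiated); set `marker_gated = FALSE` to stage on time alone.
#'
#' @param t Time(s) in hours.
#' @param marker_level Exhaustion-marker level(s) (e.g. a TOX score).
#' @param time_bounds Stage boundaries in hours. Default `c(24, 72, 120)`.
#' @param marker_threshold Early-stage marker gate. Default 0.
#' @param marker_gated Apply the marker gate? Default `TRUE`.
#' @return Character vector of labels in
#'   `{pre, early_suppression, reprogramming, late_depletion}`.
#' @export
exhaustion_stage <- function(t, marker_level = Inf,
                             time_bounds = c(24, 72, 120),
                             marker_threshold = 0, marker_gated = TRUE) {
  stopifnot(length(time_bounds) == 3L, all(diff(time_bounds) > 0))
  n <- max(length(t), length(marker_level))
  t <- rep_len(t, n); marker_level <- rep_len(marker_level, n)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (t[i] < time_bounds[1L]) "pre"
      else if (t[i] < time_bounds[2L]) {
        if (!marker_gated || marker_level[i] > marker_threshold)
          "early_suppression" else "pre"
      }
      else if (t[i] < time_bounds[3L]) "reprogramming"
      else "late_depletion"
  }
  out
}

#' Peak-to-baseline fold change of a marker series
#'
#' Ratio of the series mean over a peak window to its mean over a baseline
#' window (e.g. the 36-48 h exhaustion-marker peak against a 0-12 h
#' baseline).
#'
#' @param series Data frame with columns `time_h`, `value`.
#' @param peak_window,baseline_window Hour pairs `c(lo, hi)`; must not
#'   overlap.
#' @return Scalar fold ratio.
#' @export
peak_fold_change <- function(series, peak_window, baseline_window) {
  stopifnot(all(c("time_h", "value") %in% names(series)),
            length(peak_window) == 2L, length(baseline_window) == 2L)
  if (max(min(peak_window), min(baseline_window)) <
      min(max(peak_window), max(baseline_window)))
    stop("peak_fold_change: windows must not overlap", call. = FALSE)
  in_win <- function(w) series$time_h >= w[1L] & series$time_h <= w[2L]
  base <- mean(series$value[in_win(baseline_window)])
  peak <- mean(series$value[in_win(peak_window)])
  if (!is.finite(base) || base <= 0)
    stop("peak_fold_change: baseline mean must be positive", call. = FALSE)
  peak / base
}

#' Lead-lag estimate between two series by lagged cross-correlation
#'
#' Scans candidate lags (in grid steps, up to `max_lag` hours) of the
#' Pearson correlation between `leading` shifted forward and `lagging`,
#' then refines the discrete argmax by parabolic interpolation of the
#' correlation curve. A positive estimate means `leading` precedes
#' `lagging` by that many hours.
#'
#' @param leading,lagging Data frames `time_h`, `value` on a common uniform
#'   grid.
#' @param max_lag Largest lag magnitude scanned (hours); must be below half
#'   the series span.
#' @return List with `lag_h` (the refined estimate), `corr_at_peak`, and
#'   the discrete `lags_h`/`corr` scan.
#' @export
lead_lag_estimate <- function(leading, lagging, max_lag) {
  stopifnot(all(c("time_h", "value") %in% names(leading)),
            all(c("time_h", "value") %in% names(lagging)))
  tl <- leading$time_h
  if (length(tl) != length(lagging$time_h) ||
      max(abs(tl - lagging$time_h)) > 1e-9)
    stop("lead_lag_estimate: series must share one uniform grid",
         call. = FALSE)
  dt <- diff(tl)
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    stop("lead_lag_estimate: grid must be uniform", call. = FALSE)
  step <- dt[1L]
  span <- tl[length(tl)] - tl[1L]
  if (max_lag >= span / 2)
    stop("lead_lag_estimate: max_lag must be below half the span",
         call. = FALSE)
  if (stats::sd(leading$value) == 0 || stats::sd(lagging$value) == 0)
    stop("lead_lag_estimate: flat series, lag undefined", call. = FALSE)

  kmax <- floor(max_lag / step)
  ks <- (-kmax):kmax
  n <- length(tl)
  cc <- vapply(ks, function(k) {
    # positive k: leading shifted later by k steps aligns with lagging,
    # i.e. leading(t - k*step) vs lagging(t) on the overlap
    if (k >= 0) {
      a <- leading$value[seq_len(n - k)]
      b <- lagging$value[seq_len(n - k) + k]
    } else {
      a <- leading$value[seq_len(n + k) - k]
      b <- lagging$value[seq_len(n + k)]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }, numeric(1))

  i <- which.max(cc)
  lag <- ks[i] * step
  # parabolic sub-grid refinement on the three points around the peak
  if (i > 1L && i < length(ks) && all(is.finite(cc[(i - 1L):(i + 1L)]))) {
    y1 <- cc[i - 1L]; y2 <- cc[i]; y3 <- cc[i + 1L]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-12) {
      delta <- 0.5 * (y1 - y3) / den
      if (abs(delta) <= 1) lag <- lag + delta * step
    }
  }
  list(lag_h = lag, corr_at_peak = cc[i], lags_h = ks * step, corr = cc)
}

#' Ratio of mean pseudotime growth rates between two groups
#'
#' Each subject's trajectory (pseudotime vs hours, >= 3 points) is reduced
#' to a least-squares slope; the statistic is the ratio of group-mean
#' slopes `mean(a) / mean(b)`, with a seeded percentile bootstrap over
#' subjects for the confidence interval.
#'
#' @param group_a,group_b Lists of data frames `time_h`, `pseudotime`
#'   (e.g. sepsis as `group_a`, controls as `group_b`).
#' @param n_boot Bootstrap resamples. Default 500.
#' @param seed RNG seed.
#' @param conf Confidence level. Default 0.95.
#' @return List with `ratio`, `ci`, `slopes_a`, `slopes_b`, `n_boot`,
#'   `seed`.
#' @export
depletion_rate_ratio <- function(group_a, group_b, n_boot = 500, seed = 1,
                                 conf = 0.95) {
  slope_of <- function(df) {
    stopifnot(all(c("time_h", "pseudotime") %in% names(df)))
    if (nrow(df) < 3L)
      stop("depletion_rate_ratio: each trajectory needs >= 3 points",
           call. = FALSE)
    unname(stats::coef(stats::lm(pseudotime ~ time_h, data = df))[2L])
  }
  sa <- vapply(group_a, slope_of, numeric(1))
  sb <- vapply(group_b, slope_of, numeric(1))
  if (mean(sb) <= 0)
    stop("depletion_rate_ratio: non-positive mean slope in denominator ",
         "group", call. = FALSE)
  ratio <- mean(sa) / mean(sb)
  rs <- local_rng_state(as.integer(seed))
  on.exit(restore_rng_state(rs), add = TRUE)
  boots <- vapply(seq_len(n_boot), function(b) {
    ra <- sa[sample.int(length(sa), replace = TRUE)]
    rb <- sb[sample.int(length(sb), replace = TRUE)]
    if (mean(rb) <= 0) return(NA_real_)
    mean(ra) / mean(rb)
  }, numeric(1))
  boots <- boots[is.finite(boots)]
  alpha <- 1 - conf
  ci <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  list(ratio = ratio, ci = ci, slopes_a = sa, slopes_b = sb,
       n_boot = n_boot, seed = as.integer(seed))
}

#' Correlation between depletion rate and clinical severity
#'
#' Sample Pearson correlation between per-subject depletion rates and
#' severity scores (e.g. SOFA), with the Fisher-z confidence interval.
#'
#' @param rates,scores Equal-length numeric vectors (n >= 3, both with
#'   non-zero variance).
#' @param conf Confidence level. Default 0.95.
#' @return List with `r`, `ci`, `n`.
#' @export
severity_correlation <- function(rates, scores, conf = 0.95) {
  n <- length(rates)
  if (length(scores) != n || n < 3L)
    stop("severity_correlation: need equal lengths >= 3", call. = FALSE)
  if (stats::sd(rates) == 0 || stats::sd(scores) == 0)
    stop("severity_correlation: zero variance, correlation undefined",
         call. = FALSE)
  r <- stats::cor(rates, scores)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(c(z - q * se, z + q * se))
  list(r = r, ci = ci, n = n)
}
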