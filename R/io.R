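#' Read and write PI/AI (or single-channel) time-series CSV files
#'
#' The on-disk dialect is fixed: comma separator, `.` decimal, UTF-8, LF,
#' header exactly `time_h,PI,AI` for two-channel series or `time_h,value`
#' for single-channel series, one row per time, times strictly increasing.
#'
#' @param path File path.
#' @return `read_timeseries()`: a data frame with the validated columns.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  two <- c("time_h", "PI", "AI")
  one <- c("time_h", "value")
  if (identical(names(df)[seq_along(two)], two) && ncol(df) >= 3L) {
    df <- df[two]
  } else if (identical(names(df)[seq_along(one)], one)) {
    df <- df[one]
  } else {
    miss <- setdiff(two, names(df))
    if (length(miss) == 0L) miss <- setdiff(one, names(df))
    stop("read_timeseries: malformed header in '", path,
         "'; expected 'time_h,PI,AI' or 'time_h,value' (missing: ",
         paste(if (length(miss)) miss else "column order", collapse = ", "),
         ")", call. = FALSE)
  }
  if (any(!vapply(df, is.numeric, logical(1))))
    stop("read_timeseries: non-numeric values in '", path, "'",
         call. = FALSE)
  if (any(diff(df$time_h) <= 0))
    stop("read_timeseries: times must be strictly increasing",
         call. = FALSE)
  df
}

#' @rdname read_timeseries
#' @param series Data frame with columns `time_h,PI,AI` or `time_h,value`.
#' @return `write_timeseries()`: the path, invisibly. Values round-trip at
#'   12 significant digits.
#' @export
write_timeseries <- function(series, path) {
  ok <- identical(names(series)[1:3], c("time_h", "PI", "AI")) ||
    identical(names(series)[1:2], c("time_h", "value"))
  if (!ok)
    stop("write_timeseries: columns must be time_h,PI,AI or time_h,value",
         call. = FALSE)
  out <- as.data.frame(lapply(series, function(x) signif(x, 12)))
  names(out) <- names(series)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a cell matrix from MTX or wide CSV plus a metadata sidecar
#'
#' The sidecar CSV must have columns
#' `cell_id,time_h,genes_detected,mito_fraction` and optionally
#' `lineage_label`. For MTX input, rows are cells and a companion file
#' `<values_path>.rownames` (one cell id per line) fixes the row order; for
#' wide CSV input the first column must be `cell_id`. Sidecar rows are
#' aligned to the matrix by `cell_id`, so their order is irrelevant.
#'
#' @param values_path Path to the `.mtx` file or wide CSV.
#' @param sidecar_path Path to the metadata CSV.
#' @return A [cell_matrix()].
#' @export
read_cell_matrix <- function(values_path, sidecar_path) {
  meta <- utils::read.csv(sidecar_path, check.names = FALSE)
  need <- c("cell_id", "time_h", "genes_detected", "mito_fraction")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("read_cell_matrix: sidecar is missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(meta$cell_id))
    stop("read_cell_matrix: duplicate cell_id in sidecar", call. = FALSE)

  if (grepl("\\.mtx$", values_path)) {
    m <- as.matrix(Matrix::readMM(values_path))
    ids <- readLines(paste0(values_path, ".rownames"))
    if (length(ids) != nrow(m))
      stop("read_cell_matrix: rownames file does not match matrix rows",
           call. = FALSE)
    rownames(m) <- ids
  } else {
    df <- utils::read.csv(values_path, check.names = FALSE)
    if (names(df)[1L] != "cell_id")
      stop("read_cell_matrix: wide CSV must start with a cell_id column",
           call. = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$cell_id
  }

  if (nrow(m) != nrow(meta) ||
      length(setdiff(rownames(m), meta$cell_id)) > 0L) {
    offenders <- utils::head(c(setdiff(rownames(m), meta$cell_id),
                               setdiff(meta$cell_id, rownames(m))), 5L)
    stop("read_cell_matrix: matrix and sidecar cell ids do not match ",
         "(first offenders: ", paste(offenders, collapse = ", "), ")",
         call. = FALSE)
  }
  meta <- meta[match(rownames(m), meta$cell_id), , drop = FALSE]
  cell_matrix(m, meta$time_h, meta$genes_detected, meta$mito_fraction,
              if ("lineage_label" %in% names(meta)) meta$lineage_label,
              cell_id = meta$cell_id)
}

#' Write a cell matrix as MTX plus metadata sidecar
#'
#' @param x A [cell_matrix()].
#' @param values_path Output `.mtx` path (a `<path>.rownames` companion is
#'   written alongside).
#' @param sidecar_path Output metadata CSV path.
#' @return The `values_path`, invisibly.
#' @export
write_cell_matrix <- function(x, values_path, sidecar_path) {
  stopifnot(inherits(x, "cell_matrix"))
  Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), values_path)
  writeLines(x$cell_id, paste0(values_path, ".rownames"))
  meta <- data.frame(cell_id = x$cell_id, time_h = x$cell_time_h,
                     genes_detected = x$genes_detected,
                     mito_fraction = x$mito_fraction)
  if (!is.null(x$lineage_label)) meta$lineage_label <- x$lineage_label
  utils::write.csv(meta, sidecar_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(values_path)
}

#' Load clock parameters from a YAML mapping
#'
#' The mapping must carry keys `kpi, kpp, dpp, kai, kap, dai, theta_pi,
#' theta_ai` and may carry `n_hill` (default 2). An optional `path:` block
#' (`kind:` plus its parameters) is returned alongside.
#'
#' @param path YAML file path.
#' @return List with `params` (a [clock_params()]) and `path` (a
#'   [pathogen_load()] or `NULL`).
#' @export
read_clock_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("kpi", "kpp", "dpp", "kai", "kap", "dai",
            "theta_pi", "theta_ai")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("read_clock_config: missing key(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  params <- clock_params(y$kpi, y$kpp, y$dpp, y$kai, y$kap, y$dai,
                         y$theta_pi, y$theta_ai,
                         n_hill = if (is.null(y$n_hill)) 2 else y$n_hill)
  pl <- NULL
  if (!is.null(y$path)) {
    spec <- y$path
    kind <- spec$kind
    spec$kind <- NULL
    pl <- do.call(pathogen_load, c(list(kind = kind), spec))
  }
  list(params = params, path = pl)
}

#' Export a stochastic ensemble to CSV and JSON summaries
#'
#' Writes a wide CSV (`time_h,path_1_PI,path_1_AI,...`) and a JSON summary
#' holding per-time means and variances, stage occupancy, reversibility and
#' the seed, so a run is fully reproducible from its artifacts.
#'
#' @param ensemble A `clock_ensemble`.
#' @param setpoint A [physio_setpoint()] used for the occupancy and
#'   reversibility summaries.
#' @param csv_path,json_path Output paths.
#' @param horizon Reversibility horizon (hours); default the grid end.
#' @return `json_path`, invisibly.
#' @export
write_ensemble <- function(ensemble, setpoint, csv_path, json_path,
                           horizon = max(ensemble$t_grid)) {
  stopifnot(inherits(ensemble, "clock_ensemble"))
  np <- nrow(ensemble$PI)
  wide <- data.frame(time_h = ensemble$t_grid)
  for (i in seq_len(np)) {
    wide[[paste0("path_", i, "_PI")]] <- ensemble$PI[i, ]
    wide[[paste0("path_", i, "_AI")]] <- ensemble$AI[i, ]
  }
  utils::write.csv(wide, csv_path, row.names = FALSE, quote = FALSE)
  summ <- list(
    schema_version = 1L,
    seed = ensemble$seed,
    n_paths = np,
    noise = unclass(ensemble$noise),
    mean_PI = colMeans(ensemble$PI),
    mean_AI = colMeans(ensemble$AI),
    var_PI = apply(ensemble$PI, 2L, stats::var),
    var_AI = apply(ensemble$AI, 2L, stats::var),
    n_clamped = ensemble$n_clamped,
    occupancy = phase_occupancy(ensemble, setpoint),
    reversibility = reversibility_probability(ensemble, setpoint, horizon))
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}
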