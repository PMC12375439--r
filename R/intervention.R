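#' Cost configuration for intervention-timing optimisation
#'
#' Defines the weighted objective minimised by [optimal_time()]:
#' `L(PI(t), AI(t)) + lambda * C(t)`, where `L` is the imbalance cost
#' ([imbalance_cost()]), `C` the treatment burden ([burden()]) and
#' `lambda` in `[0, 1]` weighs safety against efficacy.
#'
#' @param lambda_weight Trade-off weight in `[0, 1]`.
#' @param setpoint A [physio_setpoint()] defining `PI_physio`, `AI_physio`.
#' @param burden_kind One of `"constant"`, `"linear_increasing"`,
#'   `"user_table"`.
#' @param burden_table Data frame `time_h`, `burden` for `"user_table"`
#'   (values >= 0, linearly interpolated).
#' @param t0,t1 Search window in hours; default 0-72 h.
#' @param mode `"pointwise"` scores the uncontrolled trajectory at `t`
#'   (the literal objective); `"counterfactual"` re-simulates with an
#'   intervention started at `t` and scores the mean imbalance over the
#'   aftermath.
#' @return An object of class `cost_config`.
#' @export
cost_config <- function(lambda_weight = 0.5, setpoint = physio_setpoint(),
                        burden_kind = c("constant", "linear_increasing",
                                        "user_table"),
                        burden_table = NULL, t0 = 0, t1 = 72,
                        mode = c("pointwise", "counterfactual")) {
  burden_kind <- match.arg(burden_kind)
  mode <- match.arg(mode)
  if (lambda_weight < 0 || lambda_weight > 1)
    stop("cost_config: lambda_weight must lie in [0, 1]", call. = FALSE)
  if (t0 >= t1) stop("cost_config: need t0 < t1", call. = FALSE)
  if (burden_kind == "user_table") {
    if (is.null(burden_table) ||
        !all(c("time_h", "burden") %in% names(burden_table)))
      stop("cost_config: user_table burden needs columns 'time_h','burden'",
           call. = FALSE)
    if (any(burden_table$burden < 0))
      stop("cost_config: burden values must be >= 0", call. = FALSE)
  }
  structure(list(lambda_weight = lambda_weight, setpoint = setpoint,
                 burden_kind = burden_kind, burden_table = burden_table,
                 t0 = t0, t1 = t1, mode = mode),
            class = "cost_config")
}

#' Immunological imbalance cost
#'
#' `L(PI, AI) = |PI - PI_physio| + |AI - AI_physio|`: the L1 distance of the
#' immune state from the healthy-control setpoint.
#'
#' @param PI,AI Mediator levels (vectorised).
#' @param setpoint A [physio_setpoint()].
#' @return Non-negative cost value(s).
#' @export
imbalance_cost <- function(PI, AI, setpoint) {
  stopifnot(inherits(setpoint, "physio_setpoint"))
  abs(PI - setpoint$PI_physio) + abs(AI - setpoint$AI_physio)
}

#' Treatment burden at a candidate intervention time
#'
#' `constant` burden is 1 everywhere; `linear_increasing` rises from 0 at
#' `t0` to 1 at `t1` (delayed intervention is costlier, e.g. accumulating
#' organ damage and ICU resource use); `user_table` interpolates a supplied
#' `(time_h, burden)` table linearly.
#'
#' @param t Time(s) in hours, inside the config window `[t0, t1]`.
#' @param config A [cost_config()].
#' @return Non-negative burden value(s).
#' @export
burden <- function(t, config) {
  stopifnot(inherits(config, "cost_config"))
  if (any(t < config$t0 - 1e-9) || any(t > config$t1 + 1e-9))
    stop("burden: t outside the window [t0, t1]", call. = FALSE)
  switch(config$burden_kind,
    constant = rep(1, length(t)),
    linear_increasing = (t - config$t0) / (config$t1 - config$t0),
    user_table = {
      tb <- config$burden_table
      stats::approx(tb$time_h, tb$burden, xout = t, rule = 2)$y
    })
}

#' Intervention as a time-windowed parameter modulation
#'
#' While active (`start <= t < start + duration`) each named clock
#' parameter is multiplied by its factor; outside the window parameters are
#' untouched. Two named presets ship with the package, realising drug
#' classes as parameter modulations (a modelling construction, with default
#' factor 0.2 for blocked production terms):
#' \describe{
#'   \item{`myd88_blockade`}{early-window innate blockade
#'     (MyD88/NF-kB axis, TNF-alpha/IL-6): scales `kpi` and `kpp` down.}
#'   \item{`checkpoint_blockade`}{intermediate-window checkpoint blockade
#'     (PD-1 axis): scales `kap` down and `dai` up, curbing the
#'     PI-driven suppressive drive and speeding AI turnover.}
#' }
#'
#' @param name Label; pass a preset name with `multipliers = NULL` to get
#'   the shipped preset.
#' @param start Start of the active window (hours).
#' @param duration Length of the active window (hours), > 0.
#' @param multipliers Named numeric vector of non-negative factors over
#'   [clock_params()] fields.
#' @return An object of class `intervention_spec`.
#' @examples
#' intervention_spec("myd88_blockade", start = 6, duration = 24)
#' @export
intervention_spec <- function(name, start = 0, duration = 24,
                              multipliers = NULL) {
  presets <- list(
    myd88_blockade = c(kpi = 0.2, kpp = 0.2),
    checkpoint_blockade = c(kap = 0.2, dai = 1.5))
  if (is.null(multipliers)) {
    if (!name %in% names(presets))
      stop("intervention_spec: unknown preset '", name, "'; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    multipliers <- presets[[name]]
  }
  if (duration <= 0)
    stop("intervention_spec: duration must be > 0", call. = FALSE)
  if (any(multipliers < 0) || is.null(names(multipliers)))
    stop("intervention_spec: multipliers must be named and >= 0",
         call. = FALSE)
  bad <- setdiff(names(multipliers),
                 c("kpi", "kpp", "dpp", "kai", "kap", "dai",
                   "theta_pi", "theta_ai", "n_hill"))
  if (length(bad))
    stop("intervention_spec: unknown parameter(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(name = name, start = start, duration = duration,
                 multipliers = multipliers),
            class = "intervention_spec")
}

#' Effective parameters under an intervention at a given time
#'
#' @param params A [clock_params()] object.
#' @param spec An [intervention_spec()].
#' @param t Time (hours).
#' @return A [clock_params()] with multipliers applied if `t` lies in
#'   `[start, start + duration)`, otherwise `params` unchanged.
#' @export
params_at_time <- function(params, spec, t) {
  stopifnot(inherits(spec, "intervention_spec"))
  if (t < spec$start || t >= spec$start + spec$duration) return(params)
  apply_intervention(params, spec)
}

#' Apply an intervention's multipliers to a parameter set
#'
#' @param params A [clock_params()] object.
#' @param spec An [intervention_spec()].
#' @return A [clock_params()] with each listed field multiplied by its
#'   factor (the time window is handled by [params_at_time()] /
#'   [integrate_clock()]).
#' @export
apply_intervention <- function(params, spec) {
  stopifnot(inherits(spec, "intervention_spec"))
  p <- unclass(params)
  for (nm in names(spec$multipliers))
    p[[nm]] <- p[[nm]] * spec$multipliers[[nm]]
  do.call(clock_params, p)
}

#' Intervention-timing objective
#'
#' Pointwise mode: `L(state at t) + lambda * C(t)` with the state linearly
#' interpolated on the uncontrolled trajectory. Counterfactual mode: the
#' trajectory is re-simulated with `intervention` started at `t`, the mean
#' imbalance cost over `[t, grid end]` replaces the pointwise `L`, and
#' `lambda * C(t)` is added.
#'
#' @param t Candidate time(s), within `[t0, t1]` and the trajectory span.
#' @param traj A `clock_trajectory` (the uncontrolled solution).
#' @param config A [cost_config()].
#' @param intervention An [intervention_spec()]; required in counterfactual
#'   mode (its `start` is overridden by `t`).
#' @return Objective value(s).
#' @export
objective <- function(t, traj, config, intervention = NULL) {
  stopifnot(inherits(traj, "clock_trajectory"),
            inherits(config, "cost_config"))
  if (config$mode == "pointwise") {
    st <- trajectory_state_at(traj, t)
    return(imbalance_cost(st$PI, st$AI, config$setpoint) +
             config$lambda_weight * burden(t, config))
  }
  if (is.null(intervention))
    stop("objective: counterfactual mode requires an intervention spec",
         call. = FALSE)
  vapply(t, function(tt) {
    spec <- intervention
    spec$start <- tt
    tg <- traj$states$time_h
    sub <- tg[tg >= tt]
    if (length(sub) < 2L || abs(sub[1L] - tt) > 1e-9)
      sub <- sort(unique(c(tt, sub)))
    st0 <- trajectory_state_at(traj, tt)
    ctr <- integrate_clock(traj$params_used, traj$path_used,
                           c(t = tt, PI = st0$PI, AI = st0$AI), sub,
                           modulation = spec)
    mean(imbalance_cost(ctr$states$PI, ctr$states$AI, config$setpoint)) +
      config$lambda_weight * burden(tt, config)
  }, numeric(1))
}

#' Optimal intervention time and near-optimal windows
#'
#' Scans the objective on a dense grid over `[t0, t1]` (default 0.1 h), then
#' refines the pointwise minimiser locally with [stats::optimize()]. Ties at
#' the minimum are broken by the earliest time. Near-optimal windows are the
#' maximal grid intervals on which the objective stays within `epsilon` of
#' the minimum (`epsilon` defaults to 5% of the objective's range over the
#' window).
#'
#' @param traj A `clock_trajectory` covering `[t0, t1]`.
#' @param config A [cost_config()].
#' @param intervention Passed to [objective()] (counterfactual mode).
#' @param grid_resolution Scan step in hours. Default 0.1.
#' @param epsilon Near-optimality margin; `NULL` for the 5%-of-range
#'   default.
#' @return An object of class `window_result`: list with `t_star`,
#'   `objective_at_star`, `windows` (data frame `lo`, `hi`), `epsilon`,
#'   `grid_resolution`, `mode`.
#' @export
optimal_time <- function(traj, config, intervention = NULL,
                         grid_resolution = 0.1, epsilon = NULL) {
  stopifnot(inherits(config, "cost_config"))
  span <- range(traj$states$time_h)
  if (config$t0 < span[1L] - 1e-9 || config$t1 > span[2L] + 1e-9)
    stop("optimal_time: trajectory does not cover [t0, t1]", call. = FALSE)
  grid <- seq(config$t0, config$t1, by = grid_resolution)
  if (grid[length(grid)] < config$t1) grid <- c(grid, config$t1)
  vals <- objective(grid, traj, config, intervention)

  i_min <- which(vals <= min(vals) + 1e-12)[1L]  # earliest tie wins
  t_star <- grid[i_min]
  obj_star <- vals[i_min]
  if (config$mode == "pointwise") {
    lo <- max(config$t0, t_star - grid_resolution)
    hi <- min(config$t1, t_star + grid_resolution)
    ref <- stats::optimize(function(tt) objective(tt, traj, config),
                           interval = c(lo, hi))
    if (ref$objective < obj_star - 1e-12) {
      t_star <- ref$minimum
      obj_star <- ref$objective
    }
  }

  rng <- diff(range(vals))
  if (is.null(epsilon)) epsilon <- 0.05 * rng
  near <- vals <= min(vals) + epsilon + 1e-12
  runs <- rle(near)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  windows <- data.frame(lo = grid[starts[keep]], hi = grid[ends[keep]])
  structure(list(t_star = t_star, objective_at_star = obj_star,
                 windows = windows, epsilon = epsilon,
                 grid_resolution = grid_resolution, mode = config$mode),
            class = "window_result")
}

#' @exportS3Method base::print
print.window_result <- function(x, ...) {
  cat(sprintf("Optimal intervention time: t* = %.3f h (objective %.5g, %s mode)\n",
              x$t_star, x$objective_at_star, x$mode))
  if (nrow(x$windows)) {
    cat(sprintf("Near-optimal windows (epsilon = %.4g):\n", x$epsilon))
    for (i in seq_len(nrow(x$windows)))
      cat(sprintf("  %.2f-%.2f h\n", x$windows$lo[i], x$windows$hi[i]))
  }
  invisible(x)
}

#' Trapezoid-integrated PI exposure of a trajectory
#'
#' Cumulative pro-inflammatory exposure, the area under PI(t); used to
#' compare intervention scenarios.
#'
#' @param traj A `clock_trajectory`.
#' @return Scalar exposure (concentration x hours).
#' @export
pi_exposure <- function(traj) {
  s <- traj$states
  sum(diff(s$time_h) * (utils::head(s$PI, -1) + utils::tail(s$PI, -1)) / 2)
}
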