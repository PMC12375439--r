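#' Right-hand side of the PI/AI immune-clock model
#'
#' Evaluates the instantaneous rates of change of the aggregate
#' pro-inflammatory (PI) and anti-inflammatory (AI) mediator levels:
#'
#' \deqn{dPI/dt = k_{pi} Path(t) + k_{pp} PI \, H(PI, \theta_{pi}) - d_{pp} PI}
#' \deqn{dAI/dt = k_{ai} Path(t) + k_{ap} PI \, H(PI, \theta_{ai}) - d_{ai} AI}
#'
#' @param t Time (hours).
#' @param PI,AI Current mediator levels (>= 0).
#' @param params A [clock_params()] object.
#' @param path A [pathogen_load()] object.
#' @return Named numeric vector `c(dPI = ..., dAI = ...)`.
#' @examples
#' p <- clock_params(1, 0, 0.3, 0.5, 0, 0.2, theta_pi = 1, theta_ai = 1)
#' clock_derivatives(0, PI = 0, AI = 0, p, pathogen_load("constant", value = 2))
#' @export
clock_derivatives <- function(t, PI, AI, params, path) {
  stopifnot(inherits(params, "clock_params"))
  load <- path_value(path, t)
  dPI <- params$kpi * load +
    params$kpp * PI * hill_activation(PI, params$theta_pi, params$n_hill) -
    params$dpp * PI
  dAI <- params$kai * load +
    params$kap * PI * hill_activation(PI, params$theta_ai, params$n_hill) -
    params$dai * AI
  c(dPI = dPI, dAI = dAI)
}

# derivative function in deSolve calling convention; `mod` optionally applies
# a time-windowed intervention (parameter multipliers) before evaluation
clock_rhs_desolve <- function(params, path, mod = NULL) {
  function(t, y, parms) {
    p <- if (is.null(mod)) params else params_at_time(params, mod, t)
    # evaluate on the clamped state so tiny negative excursions of the
    # integrator cannot feed back into the dynamics
    d <- clock_derivatives(t, max(y[1L], 0), max(y[2L], 0), p, path)
    list(d)
  }
}

#' Integrate the deterministic immune clock
#'
#' Solves the PI/AI system on a user grid with an adaptive solver
#' (deSolve; relative tolerance `1e-8` by default) and clamps states at 0
#' from below after solving. Clamping events (grid values that had to be
#' raised to 0) are counted and attached to the result.
#'
#' @param params A [clock_params()] object.
#' @param path A [pathogen_load()] object.
#' @param initial Named list or vector with `t`, `PI`, `AI` (all >= 0).
#' @param t_grid Strictly increasing times (hours) starting at `initial$t`.
#' @param rtol,atol Solver tolerances.
#' @param modulation Optional [intervention_spec()] applied while active.
#' @param method deSolve method; default `"lsoda"` (adaptive, order >= 2).
#' @return A `clock_trajectory`: list with `states`
#'   (data.frame `time_h, PI, AI`), `params_used`, `path_used`, and
#'   `n_clamped` (count of states clamped to 0).
#' @examples
#' p <- clock_params(0, 0, 0.5, 0, 0, 0.2, theta_pi = 1, theta_ai = 1)
#' tr <- integrate_clock(p, pathogen_load("constant", value = 0),
#'                       initial = c(t = 0, PI = 1, AI = 0),
#'                       t_grid = seq(0, 2, by = 0.1))
#' tail(tr$states, 1) # PI ~ exp(-1)
#' @export
integrate_clock <- function(params, path, initial, t_grid,
                            rtol = 1e-8, atol = 1e-10,
                            modulation = NULL, method = "lsoda") {
  validate_clock_params(params)
  initial <- as.list(initial)
  if (is.null(initial$t)) initial$t <- t_grid[1L]
  if (initial$PI < 0 || initial$AI < 0 || initial$t < 0)
    stop("integrate_clock: initial state must have t, PI, AI >= 0",
         call. = FALSE)
  if (abs(t_grid[1L] - initial$t) > 1e-12)
    stop("integrate_clock: t_grid must start at initial$t", call. = FALSE)
  if (length(t_grid) > 1L && any(diff(t_grid) <= 0))
    stop("integrate_clock: t_grid must be strictly increasing", call. = FALSE)

  rhs <- clock_rhs_desolve(params, path, mod = modulation)
  sol <- deSolve::ode(y = c(PI = initial$PI, AI = initial$AI),
                      times = t_grid, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  sol <- as.data.frame(unclass(sol))
  if (nrow(sol) < length(t_grid) || any(!is.finite(as.matrix(sol)))) {
    t_reached <- if (nrow(sol) > 0) max(sol$time[stats::complete.cases(sol)],
                                        -Inf) else -Inf
    stop("integrate_clock: non-finite state during integration; ",
         "last valid time ", format(t_reached), " h", call. = FALSE)
  }
  n_clamped <- sum(sol$PI < 0) + sum(sol$AI < 0)
  states <- data.frame(time_h = sol$time,
                       PI = pmax(sol$PI, 0), AI = pmax(sol$AI, 0))
  structure(list(states = states, params_used = params, path_used = path,
                 n_clamped = n_clamped),
            class = "clock_trajectory")
}

#' @exportS3Method base::print
print.clock_trajectory <- function(x, ...) {
  s <- x$states
  cat(sprintf("Immune-clock trajectory: %d states over %.3g-%.3g h\n",
              nrow(s), min(s$time_h), max(s$time_h)))
  cat(sprintf("  final PI=%.4g AI=%.4g; clamped states: %d\n",
              s$PI[nrow(s)], s$AI[nrow(s)], x$n_clamped))
  invisible(x)
}

# linear interpolation of a trajectory at arbitrary times
trajectory_state_at <- function(traj, t) {
  s <- traj$states
  if (any(t < min(s$time_h) - 1e-9) || any(t > max(s$time_h) + 1e-9))
    stop("time outside the trajectory span", call. = FALSE)
  list(PI = stats::approx(s$time_h, s$PI, xout = t, rule = 2)$y,
       AI = stats::approx(s$time_h, s$AI, xout = t, rule = 2)$y)
}

#' Equilibria of the immune clock under constant pathogen load
#'
#' Finds steady states `(PI*, AI*)` of the system by damped-Newton root
#' polishing from a deterministic grid of starting points, de-duplicates the
#' converged roots, and classifies local stability from the eigenvalues of
#' the (numerical) Jacobian.
#'
#' Because the AI equation is linear in AI given PI, the search is effectively
#' one-dimensional: for each PI root of the PI equation the matching
#' AI* is computed in closed form, then the pair is polished jointly.
#'
#' @param params A [clock_params()] object.
#' @param path_const A constant [pathogen_load()] (kind `"constant"`).
#' @param grid_max Upper end of the PI start grid; defaults to a scale set by
#'   the forcing and thresholds.
#' @param n_starts Number of grid starts.
#' @param tol Residual tolerance for accepting a root.
#' @return Data frame with columns `PI`, `AI`, `stable` (logical); zero rows
#'   if no root converged.
#' @export
steady_states <- function(params, path_const, grid_max = NULL,
                          n_starts = 40, tol = 1e-8) {
  stopifnot(inherits(path_const, "pathogen_load"))
  if (path_const$kind != "constant")
    stop("steady_states: requires a constant pathogen load", call. = FALSE)
  load <- path_const$value
  if (is.null(grid_max)) {
    scale <- max(params$theta_pi, params$theta_ai, 1)
    forced <- if (params$dpp > 0) params$kpi * load / params$dpp else 0
    grid_max <- 4 * max(scale, forced, 1)
  }
  # evaluate on the clamped state so Newton excursions below 0 stay defined
  f <- function(x) unname(clock_derivatives(0, max(x[1L], 0), max(x[2L], 0),
                                            params, path_const))
  ai_for_pi <- function(PI) {
    prod <- params$kai * load +
      params$kap * PI * hill_activation(PI, params$theta_ai, params$n_hill)
    if (params$dai > 0) prod / params$dai else NA_real_
  }
  starts <- seq(0, grid_max, length.out = n_starts)
  roots <- list()
  for (PI0 in starts) {
    AI0 <- ai_for_pi(PI0)
    if (!is.finite(AI0)) AI0 <- 0
    r <- newton_polish(f, c(PI0, AI0), tol = tol)
    if (is.null(r)) next
    if (r[1L] < -1e-9 || r[2L] < -1e-9) next
    r <- pmax(r, 0)
    if (max(abs(f(r))) > tol) next
    dup <- any(vapply(roots, function(z) max(abs(z - r)) < 1e-5, logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- r
  }
  if (length(roots) == 0L)
    return(data.frame(PI = numeric(0), AI = numeric(0), stable = logical(0)))
  out <- do.call(rbind, roots)
  stable <- apply(out, 1L, function(r) {
    J <- numeric_jacobian(f, r)
    all(Re(eigen(J, only.values = TRUE)$values) < 0)
  })
  df <- data.frame(PI = out[, 1L], AI = out[, 2L], stable = stable)
  df[order(df$PI), , drop = FALSE]
}

# damped Newton with numerical Jacobian; returns the root or NULL
newton_polish <- function(f, x0, tol = 1e-8, max_iter = 100) {
  x <- x0
  for (i in seq_len(max_iter)) {
    fx <- f(x)
    if (!all(is.finite(fx))) return(NULL)
    if (max(abs(fx)) < tol) return(x)
    J <- numeric_jacobian(f, x)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      fn <- f(xn)
      if (all(is.finite(fn)) && sum(fn^2) < sum(fx^2)) break
      lambda <- lambda / 2
      if (lambda < 1e-8) return(if (max(abs(fx)) < sqrt(tol)) x else NULL)
    }
    x <- xn
  }
  if (max(abs(f(x))) < tol) x else NULL
}

numeric_jacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), n)
  for (j in seq_len(n)) {
    dx <- max(abs(x[j]), 1) * h
    xp <- x; xp[j] <- xp[j] + dx
    xm <- x; xm[j] <- xm[j] - dx
    J[, j] <- (f(xp) - f(xm)) / (2 * dx)
  }
  J
}

#' Classify an immune state into a clock phase
#'
#' A state is `homeostasis` when both PI and AI lie inside the setpoint band.
#' Otherwise the PI/AI balance ratio `R = PI / (AI + eps)` decides:
#' `R > upper` is `hyperinflammatory`, `R < lower` is `immunosuppressive`,
#' and anything between is `transitional`.
#'
#' @param PI,AI Mediator levels (vectorised, equal length).
#' @param setpoint A [physio_setpoint()].
#' @param ratio_thresholds Numeric pair `c(lower, upper)`; default
#'   `c(0.5, 2)`.
#' @param eps Ratio regulariser. Default `1e-8`.
#' @return Character vector of labels.
#' @export
classify_phase <- function(PI, AI, setpoint,
                           ratio_thresholds = c(0.5, 2), eps = 1e-8) {
  stopifnot(inherits(setpoint, "physio_setpoint"),
            length(ratio_thresholds) == 2L,
            ratio_thresholds[1L] < ratio_thresholds[2L])
  bw <- setpoint$band_halfwidth
  in_band <- abs(PI - setpoint$PI_physio) <= bw &
    abs(AI - setpoint$AI_physio) <= bw
  R <- PI / (AI + eps)
  out <- ifelse(R > ratio_thresholds[2L], "hyperinflammatory",
         ifelse(R < ratio_thresholds[1L], "immunosuppressive",
                "transitional"))
  out[in_band] <- "homeostasis"
  out
}

#' Onset time of the anti-inflammatory response
#'
#' The delay from onset to initiation of the anti-inflammatory response
#' (`t_ai`) is read off a trajectory as the earliest time at which AI
#' reaches a fraction `q` of its trajectory maximum, linearly interpolated
#' between grid points.
#'
#' @param traj A `clock_trajectory`.
#' @param q Fraction of the AI maximum defining "initiation" (0 < q < 1).
#'   Default 0.1.
#' @return Onset time in hours, or `NA_real_` when AI is identically 0.
#' @export
anti_inflammatory_onset <- function(traj, q = 0.1) {
  stopifnot(inherits(traj, "clock_trajectory"), q > 0, q < 1)
  s <- traj$states
  if (nrow(s) == 0L) stop("anti_inflammatory_onset: empty trajectory",
                          call. = FALSE)
  peak <- max(s$AI)
  if (peak <= 0) return(NA_real_)
  thr <- q * peak
  above <- which(s$AI >= thr)
  if (length(above) == 0L) return(NA_real_)
  i <- above[1L]
  if (i == 1L) return(s$time_h[1L])
  # linear interpolation on the crossing segment
  t0 <- s$time_h[i - 1L]; t1 <- s$time_h[i]
  y0 <- s$AI[i - 1L];     y1 <- s$AI[i]
  t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
}

#' Fit immune-clock parameters to an observed PI/AI time series
#'
#' Bounded multi-start Levenberg-Marquardt least squares
#' (via \pkg{minpack.lm}) on the stacked PI and AI residuals between
#' [integrate_clock()] output and the observations. Starts are the initial
#' guess plus log-scale perturbations drawn from a fixed internal RNG stream,
#' so the fit is deterministic. Ties are broken by lowest residual, then
#' lowest parameter L2 norm.
#'
#' @param observed Data frame with columns `time_h`, `PI`, `AI` (strictly
#'   increasing times).
#' @param path The [pathogen_load()] forcing assumed during observation.
#' @param initial_guess A [clock_params()] object used as the centre of the
#'   start set (and returned verbatim for degenerate all-zero data).
#' @param lower,upper Named numeric vectors of box bounds for free
#'   parameters; defaults 0 (1e-4 for thresholds) and 10.
#' @param fixed Character vector naming parameters held at their
#'   `initial_guess` value. Default fixes the two thresholds and `n_hill`.
#' @param initial_state Initial `(PI, AI)` at `observed$time_h[1]`; defaults
#'   to the first observed row.
#' @param n_starts Number of multi-starts. Default 5.
#' @return List with `params` (a [clock_params()]), `rss`, `free` (names of
#'   fitted parameters), `non_identifiable` flag, and `n_starts_converged`.
#' @export
fit_parameters <- function(observed, path, initial_guess,
                           lower = NULL, upper = NULL,
                           fixed = c("theta_pi", "theta_ai", "n_hill"),
                           initial_state = NULL, n_starts = 5) {
  stopifnot(all(c("time_h", "PI", "AI") %in% names(observed)))
  validate_clock_params(initial_guess)
  all_names <- c("kpi", "kpp", "dpp", "kai", "kap", "dai",
                 "theta_pi", "theta_ai", "n_hill")
  fixed <- intersect(fixed, all_names)
  free <- setdiff(all_names, fixed)
  if (nrow(observed) < 2 * length(free))
    stop("fit_parameters: need at least 2x more observations than free ",
         "parameters", call. = FALSE)
  if (is.null(initial_state))
    initial_state <- c(t = observed$time_h[1L],
                       PI = observed$PI[1L], AI = observed$AI[1L])

  # degenerate data: everything zero under zero forcing fits any parameters
  if (all(observed$PI == 0) && all(observed$AI == 0) &&
      all(path_value(path, observed$time_h) == 0) &&
      initial_state[["PI"]] == 0 && initial_state[["AI"]] == 0) {
    return(list(params = initial_guess, rss = 0, free = free,
                non_identifiable = TRUE, n_starts_converged = 0L))
  }

  lo <- c(kpi = 0, kpp = 0, dpp = 0, kai = 0, kap = 0, dai = 0,
          theta_pi = 1e-4, theta_ai = 1e-4, n_hill = 1)
  hi <- c(kpi = 10, kpp = 10, dpp = 10, kai = 10, kap = 10, dai = 10,
          theta_pi = 10, theta_ai = 10, n_hill = 6)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  resid_fn <- function(theta) {
    p <- initial_guess
    p[free] <- as.list(pmin(pmax(theta, lo[free]), hi[free]))
    tr <- tryCatch(
      integrate_clock(p, path, initial_state, observed$time_h,
                      rtol = 1e-7, atol = 1e-9),
      error = function(e) NULL)
    if (is.null(tr)) return(rep(1e6, 2L * nrow(observed)))
    c(tr$states$PI - observed$PI, tr$states$AI - observed$AI)
  }

  guess0 <- unlist(initial_guess[free])
  # deterministic start set: the guess itself plus seeded log-normal jitter
  starts <- list(guess0)
  if (n_starts > 1) {
    rs <- local_rng_state(20260901L)
    on.exit(restore_rng_state(rs), add = TRUE)
    for (i in seq_len(n_starts - 1L)) {
      jit <- guess0 * exp(stats::rnorm(length(guess0), 0, 0.5))
      jit[guess0 == 0] <- abs(stats::rnorm(sum(guess0 == 0), 0, 0.1))
      starts[[i + 1L]] <- pmin(pmax(jit, lo[free]), hi[free])
    }
  }

  best <- NULL
  n_ok <- 0L
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s0, fn = resid_fn,
                         lower = lo[free], upper = hi[free],
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    rss <- sum(fit$fvec^2)
    cand <- list(par = fit$par, rss = rss, norm = sqrt(sum(fit$par^2)))
    if (is.null(best) || cand$rss < best$rss - 1e-14 ||
        (abs(cand$rss - best$rss) <= 1e-14 && cand$norm < best$norm))
      best <- cand
  }
  if (is.null(best))
    stop("fit_parameters: all ", length(starts), " starts failed to ",
         "converge", call. = FALSE)
  p <- initial_guess
  p[free] <- as.list(unname(best$par))
  list(params = do.call(clock_params, p), rss = best$rss, free = free,
       non_identifiable = FALSE, n_starts_converged = n_ok)
}

# save/restore the global RNG state so internal seeding is invisible to users
local_rng_state <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
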