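#' Noise configuration for the stochastic immune clock
#'
#' @param sigma_pi,sigma_ai Noise intensities (per sqrt-hour), >= 0.
#' @param scheme `"multiplicative"` (state-proportional diffusion,
#'   `sigma * X dW`) or `"additive"` (`sigma dW`). Multiplicative is the
#'   default: it keeps relative fluctuations scale-free and preserves the
#'   positivity boundary naturally.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(sigma_pi = 0.05, sigma_ai = 0.05,
                         scheme = c("multiplicative", "additive")) {
  scheme <- match.arg(scheme)
  if (sigma_pi < 0 || sigma_ai < 0)
    stop("noise_config: noise intensities must be >= 0", call. = FALSE)
  structure(list(sigma_pi = sigma_pi, sigma_ai = sigma_ai, scheme = scheme),
            class = "noise_config")
}

#' Simulate a stochastic ensemble of immune-clock paths
#'
#' Euler-Maruyama integration of
#' `dX = f(X, t) dt + sigma(X) dW` with drift `f` given by
#' [clock_derivatives()]. Diffusion is `(sigma_pi, sigma_ai)` for the
#' additive scheme and `(sigma_pi * PI, sigma_ai * AI)` for the
#' multiplicative scheme. Negative excursions are reflected by clamping to
#' 0; the number of clamped increments is recorded. The ensemble is a pure
#' function of `(seed, n_paths, t_grid, configs)`.
#'
#' @param params A [clock_params()] object.
#' @param path A [pathogen_load()] forcing.
#' @param initial Named vector/list with `t`, `PI`, `AI`.
#' @param noise A [noise_config()].
#' @param t_grid Fixed-step, strictly increasing hour grid.
#' @param n_paths Number of sample paths (>= 1).
#' @param seed Integer RNG seed.
#' @return An object of class `clock_ensemble`: list with `t_grid`,
#'   matrices `PI` and `AI` (`n_paths x length(t_grid)`), `n_clamped`,
#'   `seed`, `noise`, `params`, `path`.
#' @export
simulate_sde <- function(params, path, initial, noise, t_grid,
                         n_paths = 100, seed = 1) {
  validate_clock_params(params)
  stopifnot(inherits(noise, "noise_config"), n_paths >= 1)
  initial <- as.list(initial)
  nt <- length(t_grid)
  if (nt < 2L || any(diff(t_grid) <= 0))
    stop("simulate_sde: t_grid must be strictly increasing with >= 2 points",
         call. = FALSE)
  dt <- diff(t_grid)
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    stop("simulate_sde: t_grid must have a fixed step", call. = FALSE)

  rs <- local_rng_state(as.integer(seed))
  on.exit(restore_rng_state(rs), add = TRUE)

  PI <- matrix(NA_real_, n_paths, nt)
  AI <- matrix(NA_real_, n_paths, nt)
  PI[, 1L] <- initial$PI
  AI[, 1L] <- initial$AI
  n_clamped <- 0L
  mult <- noise$scheme == "multiplicative"
  loads <- path_value(path, t_grid)

  for (k in seq_len(nt - 1L)) {
    h <- dt[k]
    pi_k <- PI[, k]; ai_k <- AI[, k]
    hp <- hill_activation(pi_k, params$theta_pi, params$n_hill)
    ha <- hill_activation(pi_k, params$theta_ai, params$n_hill)
    f_pi <- params$kpi * loads[k] + params$kpp * pi_k * hp -
      params$dpp * pi_k
    f_ai <- params$kai * loads[k] + params$kap * pi_k * ha -
      params$dai * ai_k
    g_pi <- if (mult) noise$sigma_pi * pi_k else rep(noise$sigma_pi, n_paths)
    g_ai <- if (mult) noise$sigma_ai * ai_k else rep(noise$sigma_ai, n_paths)
    dw_pi <- stats::rnorm(n_paths, 0, sqrt(h))
    dw_ai <- stats::rnorm(n_paths, 0, sqrt(h))
    new_pi <- pi_k + f_pi * h + g_pi * dw_pi
    new_ai <- ai_k + f_ai * h + g_ai * dw_ai
    n_clamped <- n_clamped + sum(new_pi < 0) + sum(new_ai < 0)
    PI[, k + 1L] <- pmax(new_pi, 0)
    AI[, k + 1L] <- pmax(new_ai, 0)
    if (any(!is.finite(PI[, k + 1L])) || any(!is.finite(AI[, k + 1L]))) {
      bad <- which(!is.finite(PI[, k + 1L]) | !is.finite(AI[, k + 1L]))[1L]
      stop("simulate_sde: non-finite value on path ", bad, " at t = ",
           format(t_grid[k + 1L]), " h", call. = FALSE)
    }
  }
  structure(list(t_grid = t_grid, PI = PI, AI = AI, n_clamped = n_clamped,
                 seed = as.integer(seed), noise = noise, params = params,
                 path = path),
            class = "clock_ensemble")
}

#' @exportS3Method base::print
print.clock_ensemble <- function(x, ...) {
  cat(sprintf("Immune-clock ensemble: %d paths x %d times (%.3g-%.3g h)\n",
              nrow(x$PI), length(x$t_grid), min(x$t_grid), max(x$t_grid)))
  cat(sprintf("  seed %d, %s noise (sigma_pi=%.3g, sigma_ai=%.3g), ",
              x$seed, x$noise$scheme, x$noise$sigma_pi, x$noise$sigma_ai))
  cat(sprintf("clamped increments: %d\n", x$n_clamped))
  invisible(x)
}

# per-path, per-time stage label used by phase_occupancy:
#   reversible   - currently inside the homeostasis band
#   stable       - outside the band with |d state/dt| below rate_tol
#   transitional - otherwise
ensemble_stages <- function(ensemble, setpoint, rate_tol = 0.02) {
  tg <- ensemble$t_grid
  dt <- diff(tg)
  bw <- setpoint$band_halfwidth
  in_band <- abs(ensemble$PI - setpoint$PI_physio) <= bw &
    abs(ensemble$AI - setpoint$AI_physio) <= bw
  # centred finite-difference speed along each path (forward/backward at ends)
  speed_of <- function(M) {
    n <- ncol(M)
    sp <- matrix(NA_real_, nrow(M), n)
    sp[, 1L] <- abs(M[, 2L] - M[, 1L]) / dt[1L]
    sp[, n] <- abs(M[, n] - M[, n - 1L]) / dt[n - 1L]
    if (n > 2L)
      sp[, 2:(n - 1L)] <- abs(M[, 3:n] - M[, 1:(n - 2L)]) /
        rep(tg[3:n] - tg[1:(n - 2L)], each = nrow(M))
    sp
  }
  slow <- pmax(speed_of(ensemble$PI), speed_of(ensemble$AI)) < rate_tol
  stage <- matrix("transitional", nrow(ensemble$PI), ncol(ensemble$PI))
  stage[slow & !in_band] <- "stable"
  stage[in_band] <- "reversible"
  stage
}

#' Stage occupancy of a stochastic ensemble over time bins
#'
#' For each time bin, the fraction of path-time points in each kinetic
#' stage: `reversible` (inside the homeostasis band), `stable` (outside the
#' band and nearly stationary), `transitional` (otherwise). Default bin
#' edges follow the three-stage partition of the response: early reversible
#' (0-24 h), intermediate transitional (24-72 h), late stable (> 72 h).
#'
#' @param ensemble A `clock_ensemble` from [simulate_sde()].
#' @param setpoint A [physio_setpoint()].
#' @param stage_bounds Hour pair splitting early/intermediate/late bins.
#'   Default `c(24, 72)`.
#' @param rate_tol State-speed threshold (units/h) below which an
#'   out-of-band path counts as `stable`. Default 0.02.
#' @return Data frame with `bin_lo`, `bin_hi`, `reversible`, `transitional`,
#'   `stable`; the three fractions sum to 1 in every bin.
#' @export
phase_occupancy <- function(ensemble, setpoint, stage_bounds = c(24, 72),
                            rate_tol = 0.02) {
  stopifnot(inherits(ensemble, "clock_ensemble"),
            inherits(setpoint, "physio_setpoint"),
            length(stage_bounds) == 2L, stage_bounds[1L] < stage_bounds[2L])
  tg <- ensemble$t_grid
  edges <- unique(sort(c(min(tg), stage_bounds, max(tg))))
  edges <- edges[edges >= min(tg) & edges <= max(tg)]
  if (length(edges) < 2L) edges <- range(tg)
  stage <- ensemble_stages(ensemble, setpoint, rate_tol)
  out <- data.frame()
  for (b in seq_len(length(edges) - 1L)) {
    lo <- edges[b]; hi <- edges[b + 1L]
    sel <- if (b == length(edges) - 1L) tg >= lo & tg <= hi
           else tg >= lo & tg < hi
    sub <- stage[, sel, drop = FALSE]
    n <- length(sub)
    out <- rbind(out, data.frame(
      bin_lo = lo, bin_hi = hi,
      reversible = sum(sub == "reversible") / n,
      transitional = sum(sub == "transitional") / n,
      stable = sum(sub == "stable") / n))
  }
  out
}

#' Probability that a stochastic path remains recoverable
#'
#' Fraction of ensemble paths that re-enter the homeostasis band at some
#' time at or before `horizon` and then stay inside it through the end of
#' the grid, with a Wilson 95% binomial confidence interval.
#'
#' @param ensemble A `clock_ensemble`.
#' @param setpoint A [physio_setpoint()].
#' @param horizon Latest re-entry time considered (hours); must lie within
#'   the ensemble grid.
#' @return List with `probability`, `ci` (length-2), `n_paths`,
#'   `n_reversible`.
#' @export
reversibility_probability <- function(ensemble, setpoint, horizon) {
  stopifnot(inherits(ensemble, "clock_ensemble"))
  tg <- ensemble$t_grid
  if (horizon < min(tg) || horizon > max(tg))
    stop("reversibility_probability: horizon outside the ensemble grid",
         call. = FALSE)
  bw <- setpoint$band_halfwidth
  in_band <- abs(ensemble$PI - setpoint$PI_physio) <= bw &
    abs(ensemble$AI - setpoint$AI_physio) <= bw
  ok <- vapply(seq_len(nrow(in_band)), function(i) {
    row <- in_band[i, ]
    # last exit from the band; path qualifies if the final in-band stretch
    # starts at or before the horizon
    if (!row[length(row)]) return(FALSE)
    outside <- which(!row)
    entry <- if (length(outside) == 0L) 1L else max(outside) + 1L
    tg[entry] <= horizon
  }, logical(1))
  k <- sum(ok); n <- length(ok)
  list(probability = k / n, ci = wilson_interval(k, n),
       n_paths = n, n_reversible = k)
}

# Wilson score interval at 95%
wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}
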