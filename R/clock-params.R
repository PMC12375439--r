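#' Rate and threshold constants of the PI/AI immune-clock model
#'
#' Bundles the kinetic constants of the reduced two-state model of aggregate
#' pro-inflammatory (PI) and anti-inflammatory (AI) mediator dynamics:
#'
#' \deqn{dPI/dt = k_{pi} Path(t) + k_{pp} PI \, H(PI, \theta_{pi}) - d_{pp} PI}
#' \deqn{dAI/dt = k_{ai} Path(t) + k_{ap} PI \, H(PI, \theta_{ai}) - d_{ai} AI}
#'
#' where `Path(t)` is the external pathogen load and `H` the activating Hill
#' function [hill_activation()]. The `H(PI, theta_ai)` gate in the AI
#' equation is taken literally: AI production driven by PI is switched on
#' when PI itself crosses `theta_ai`.
#'
#' @param kpi PI production rate per unit pathogen load (1/h).
#' @param kpp PI self-amplification rate (1/h).
#' @param dpp PI decay rate (1/h).
#' @param kai AI production rate per unit pathogen load (1/h).
#' @param kap PI-driven AI production rate (1/h).
#' @param dai AI decay rate (1/h).
#' @param theta_pi Hill threshold for PI self-amplification (concentration).
#' @param theta_ai Hill threshold gating PI-driven AI production
#'   (concentration).
#' @param n_hill Hill exponent (dimensionless, >= 1). Default 2.
#' @return An object of class `clock_params` (named list).
#' @examples
#' p <- clock_params(kpi = 0.8, kpp = 0.3, dpp = 0.45,
#'                   kai = 0.1, kap = 0.35, dai = 0.2,
#'                   theta_pi = 1.2, theta_ai = 1.5)
#' @export
clock_params <- function(kpi, kpp, dpp, kai, kap, dai,
                         theta_pi, theta_ai, n_hill = 2) {
  p <- list(kpi = kpi, kpp = kpp, dpp = dpp,
            kai = kai, kap = kap, dai = dai,
            theta_pi = theta_pi, theta_ai = theta_ai, n_hill = n_hill)
  validate_clock_params(p)
  structure(p, class = "clock_params")
}

validate_clock_params <- function(p) {
  rates <- c("kpi", "kpp", "dpp", "kai", "kap", "dai")
  for (nm in rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("clock_params: rate '", nm, "' must be a finite scalar >= 0",
           call. = FALSE)
  }
  for (nm in c("theta_pi", "theta_ai")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("clock_params: threshold '", nm, "' must be > 0", call. = FALSE)
  }
  if (!is.numeric(p$n_hill) || length(p$n_hill) != 1L || p$n_hill < 1)
    stop("clock_params: 'n_hill' must be >= 1", call. = FALSE)
  invisible(p)
}

#' @exportS3Method base::print
print.clock_params <- function(x, ...) {
  cat("PI/AI immune-clock parameters\n")
  cat(sprintf("  PI: kpi=%.4g kpp=%.4g dpp=%.4g (theta_pi=%.4g)\n",
              x$kpi, x$kpp, x$dpp, x$theta_pi))
  cat(sprintf("  AI: kai=%.4g kap=%.4g dai=%.4g (theta_ai=%.4g)\n",
              x$kai, x$kap, x$dai, x$theta_ai))
  cat(sprintf("  Hill exponent n=%.4g\n", x$n_hill))
  invisible(x)
}

#' Activating Hill function
#'
#' `H(x) = x^n / (x^n + theta^n)`: fraction of maximal activation at
#' concentration `x`, with half-saturation at `x = theta` and steepness `n`.
#'
#' @param x Concentration(s), >= 0. Vectorised.
#' @param theta Half-saturation threshold, > 0.
#' @param n Hill exponent, >= 1.
#' @return Activation fraction(s) in `[0, 1]`.
#' @examples
#' hill_activation(3, theta = 1, n = 2) # 0.9
#' @export
hill_activation <- function(x, theta, n) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta <= 0)
    stop("hill_activation: 'theta' must be a finite scalar > 0",
         call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("hill_activation: 'n' must be a finite scalar >= 1", call. = FALSE)
  if (any(x < 0)) stop("hill_activation: 'x' must be >= 0", call. = FALSE)
  # compute on the ratio scale so large x^n cannot overflow
  r <- (x / theta)^n
  ifelse(is.infinite(r), 1, r / (1 + r))
}

#' Pathogen-load forcing input
#'
#' The reduced clock treats the pathogen burden as an external input rather
#' than a modelled state. Three kinds are supported:
#' \describe{
#'   \item{`constant`}{`Path(t) = value`.}
#'   \item{`logistic_with_clearance`}{logistic growth
#'     `P0 e^{gt} / (1 + (P0/K)(e^{gt} - 1))` multiplied by an exponential
#'     clearance factor `e^{-c max(0, t - t_clear)}` that switches on at
#'     `t_clear` (antibiotics / immune clearance).}
#'   \item{`sampled`}{a measured series `(time_h, value)`, linearly
#'     interpolated and held constant beyond its ends.}
#' }
#'
#' @param kind One of `"constant"`, `"logistic_with_clearance"`, `"sampled"`.
#' @param value Load for `kind = "constant"`.
#' @param P0,g,K Initial load, growth rate (1/h) and carrying capacity for
#'   the logistic kind.
#' @param t_clear,c_clear Clearance onset (h) and clearance rate (1/h).
#' @param series Data frame with columns `time_h`, `value` for
#'   `kind = "sampled"`; times strictly increasing, values >= 0.
#' @return An object of class `pathogen_load`; evaluate it with
#'   [path_value()].
#' @examples
#' pl <- pathogen_load("logistic_with_clearance", P0 = 0.05, g = 0.4,
#'                     K = 3, t_clear = 20, c_clear = 0.15)
#' path_value(pl, c(0, 12, 48))
#' @export
pathogen_load <- function(kind = c("constant", "logistic_with_clearance",
                                   "sampled"),
                          value = 1, P0 = 0.05, g = 0.4, K = 3,
                          t_clear = Inf, c_clear = 0, series = NULL) {
  kind <- match.arg(kind)
  obj <- switch(kind,
    constant = {
      if (value < 0) stop("pathogen_load: constant value must be >= 0",
                          call. = FALSE)
      list(kind = kind, value = value)
    },
    logistic_with_clearance = {
      if (P0 < 0 || K <= 0 || c_clear < 0)
        stop("pathogen_load: need P0 >= 0, K > 0, c_clear >= 0",
             call. = FALSE)
      list(kind = kind, P0 = P0, g = g, K = K,
           t_clear = t_clear, c_clear = c_clear)
    },
    sampled = {
      if (is.null(series) || !all(c("time_h", "value") %in% names(series)))
        stop("pathogen_load: sampled kind needs a series with columns ",
             "'time_h' and 'value'", call. = FALSE)
      if (any(diff(series$time_h) <= 0))
        stop("pathogen_load: sampled times must be strictly increasing",
             call. = FALSE)
      if (any(series$value < 0))
        stop("pathogen_load: sampled load values must be >= 0",
             call. = FALSE)
      list(kind = kind, series = as.data.frame(series)[c("time_h", "value")])
    })
  structure(obj, class = "pathogen_load")
}

#' Evaluate a pathogen-load input at given times
#'
#' @param path A [pathogen_load()] object.
#' @param t Time(s) in hours.
#' @return Non-negative load value(s), same length as `t`.
#' @export
path_value <- function(path, t) {
  stopifnot(inherits(path, "pathogen_load"))
  switch(path$kind,
    constant = rep(path$value, length(t)),
    logistic_with_clearance = {
      e <- exp(path$g * t)
      base <- path$P0 * e / (1 + (path$P0 / path$K) * (e - 1))
      base[!is.finite(base)] <- path$K  # logistic saturates at K
      clear <- exp(-path$c_clear * pmax(0, t - path$t_clear))
      pmax(0, base * clear)
    },
    sampled = {
      s <- path$series
      stats::approx(s$time_h, s$value, xout = t, rule = 2)$y
    })
}

#' Homeostatic setpoint and tolerance band
#'
#' The healthy-control operating point of the PI/AI system, with a symmetric
#' band of half-width `band_halfwidth` around each coordinate inside which a
#' state counts as homeostatic.
#'
#' @param PI_physio,AI_physio Homeostatic PI and AI levels (>= 0).
#' @param band_halfwidth Half-width of the homeostasis band (> 0).
#' @return An object of class `physio_setpoint`.
#' @export
physio_setpoint <- function(PI_physio = 1, AI_physio = 1,
                            band_halfwidth = 0.25) {
  if (PI_physio < 0 || AI_physio < 0)
    stop("physio_setpoint: setpoint levels must be >= 0", call. = FALSE)
  if (band_halfwidth <= 0)
    stop("physio_setpoint: band_halfwidth must be > 0", call. = FALSE)
  structure(list(PI_physio = PI_physio, AI_physio = AI_physio,
                 band_halfwidth = band_halfwidth),
            class = "physio_setpoint")
}
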