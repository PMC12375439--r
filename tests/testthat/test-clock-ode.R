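test_that("Hill activation has the stated bounds, half-saturation and monotonicity", {
  expect_equal(hill_activation(0, 1, 2), 0)
  expect_equal(hill_activation(3, 1, 2), 0.9)
  for (n in c(1, 2, 4.5)) for (theta in c(0.5, 1, 3))
    expect_equal(hill_activation(theta, theta, n), 0.5)
  x <- seq(0, 20, by = 0.05)
  h <- hill_activation(x, theta = 1.7, n = 3)
  expect_true(all(h >= 0 & h <= 1))
  expect_true(all(diff(h) >= 0))
  expect_error(hill_activation(1, theta = 0, n = 2), "theta")
  expect_error(hill_activation(1, theta = 1, n = 0.5), "'n'")
  expect_error(hill_activation(-1, theta = 1, n = 2), "x")
})

test_that("clock derivatives match direct substitution", {
  origin <- clock_derivatives(0, PI = 0, AI = 0, demo_params(),
                              pathogen_load("constant", value = 0))
  expect_equal(unname(origin), c(0, 0))

  p <- clock_params(kpi = 1, kpp = 0, dpp = 0, kai = 0.5, kap = 0, dai = 0,
                    theta_pi = 1, theta_ai = 1)
  d <- clock_derivatives(0, PI = 0, AI = 0, p,
                         pathogen_load("constant", value = 2))
  expect_equal(unname(d), c(2, 1))

  p2 <- clock_params(kpi = 0, kpp = 0, dpp = 0.3, kai = 0, kap = 0,
                     dai = 0.2, theta_pi = 1, theta_ai = 1)
  d2 <- clock_derivatives(5, PI = 1, AI = 1, p2,
                          pathogen_load("constant", value = 0))
  expect_equal(unname(d2), c(-0.3, -0.2))
})

test_that("integration reproduces closed forms and freezes under zero rates", {
  p <- clock_params(0, 0, 0.5, 0, 0, 0.2, theta_pi = 1, theta_ai = 1)
  tr <- integrate_clock(p, pathogen_load("constant", value = 0),
                        c(t = 0, PI = 1, AI = 0), seq(0, 2, by = 0.1))
  expect_equal(tr$states$PI[tr$states$time_h == 2], exp(-1),
               tolerance = 1e-6)

  p0 <- clock_params(0, 0, 0, 0, 0, 0, theta_pi = 1, theta_ai = 1)
  tr0 <- integrate_clock(p0, pathogen_load("constant", value = 3),
                         c(t = 0, PI = 0.7, AI = 1.3), seq(0, 10, by = 0.5))
  expect_equal(tr0$states$PI, rep(0.7, 21))
  expect_equal(tr0$states$AI, rep(1.3, 21))
})

test_that("linear-limit solution matches the forced-decay closed form", {
  # kpp = kap = 0 decouples both equations into forced linear decay
  p <- clock_params(kpi = 0.6, kpp = 0, dpp = 0.4, kai = 0.25, kap = 0,
                    dai = 0.15, theta_pi = 1, theta_ai = 1)
  cload <- 1.8
  tg <- seq(0, 30, by = 0.1)
  tr <- integrate_clock(p, pathogen_load("constant", value = cload),
                        c(t = 0, PI = 0.2, AI = 2), tg)
  pi_star <- p$kpi * cload / p$dpp
  ai_star <- p$kai * cload / p$dai
  expect_equal(tr$states$PI, pi_star + (0.2 - pi_star) * exp(-p$dpp * tg),
               tolerance = 1e-5)
  expect_equal(tr$states$AI, ai_star + (2 - ai_star) * exp(-p$dai * tg),
               tolerance = 1e-5)
})

test_that("solutions stay non-negative and self-converge under refinement", {
  tg <- seq(0, 100, by = 0.1)
  tr <- demo_trajectory()
  expect_true(all(tr$states$PI >= 0))
  expect_true(all(tr$states$AI >= 0))

  ref <- integrate_clock(demo_params(), demo_path(), c(t = 0, PI = 0, AI = 0),
                         seq(0, 100, by = 0.001))
  on_grid <- ref$states[ref$states$time_h %in% round(tg, 10), ]
  expect_lt(max(abs(tr$states$PI - approx(ref$states$time_h, ref$states$PI,
                                          xout = tg)$y)), 1e-4)
  expect_lt(max(abs(tr$states$AI - approx(ref$states$time_h, ref$states$AI,
                                          xout = tg)$y)), 1e-4)

  # fixed-step scheme is order >= 2: halving the step shrinks the error by
  # more than a factor of 4
  err_at <- function(h) {
    sol <- integrate_clock(demo_params(), demo_path(),
                           c(t = 0, PI = 0, AI = 0), seq(0, 24, by = h),
                           method = "rk4")
    idx <- match(round(sol$states$time_h, 10),
                 round(ref$states$time_h, 10))
    max(abs(sol$states$PI - ref$states$PI[idx]))
  }
  expect_gt(err_at(0.4) / err_at(0.2), 4)
})

test_that("steady states match closed forms and verify by substitution", {
  # linear case: unique equilibrium (kpi c / dpp, kai c / dai)
  p <- clock_params(1, 0, 0.3, 0.5, 0, 0.2, theta_pi = 1, theta_ai = 1)
  ss <- steady_states(p, pathogen_load("constant", value = 2))
  expect_equal(nrow(ss), 1L)
  expect_equal(ss$PI, 2 / 0.3, tolerance = 1e-6)
  expect_equal(ss$AI, 0.5 * 2 / 0.2, tolerance = 1e-6)
  expect_true(ss$stable)

  # origin-only with decay
  p0 <- clock_params(0, 0, 0.5, 0, 0, 0.2, theta_pi = 1, theta_ai = 1)
  ss0 <- steady_states(p0, pathogen_load("constant", value = 0))
  expect_equal(nrow(ss0), 1L)
  expect_equal(c(ss0$PI, ss0$AI), c(0, 0))
  expect_true(ss0$stable)

  # self-amplifying regime: origin plus a positive-PI equilibrium, each
  # verified by direct substitution into the derivatives
  pb <- clock_params(0, 2, 0.5, 0, 0, 0.2, theta_pi = 1, theta_ai = 1,
                     n_hill = 2)
  ssb <- steady_states(pb, pathogen_load("constant", value = 0))
  expect_gte(nrow(ssb), 2L)
  expect_true(any(ssb$PI > 1e-3))
  for (i in seq_len(nrow(ssb))) {
    d <- clock_derivatives(0, ssb$PI[i], ssb$AI[i], pb,
                           pathogen_load("constant", value = 0))
    expect_lt(max(abs(d)), 1e-6)
  }
})

test_that("phase classification follows the band and the balance ratio", {
  sp <- physio_setpoint(1, 1, band_halfwidth = 0.25)
  expect_equal(classify_phase(1, 1, sp), "homeostasis")
  expect_equal(classify_phase(10, 1, sp), "hyperinflammatory")
  expect_equal(classify_phase(0.1, 5, sp), "immunosuppressive")
  expect_equal(classify_phase(2, 2, sp), "transitional")
  # vectorised, custom thresholds
  out <- classify_phase(c(1, 8, 1.2), c(1, 0.5, 4), sp,
                        ratio_thresholds = c(0.25, 4))
  expect_equal(out, c("homeostasis", "hyperinflammatory", "transitional"))
})

test_that("anti-inflammatory onset interpolates the threshold crossing", {
  ramp <- as_trajectory(data.frame(time_h = 0:10, PI = 0, AI = 0:10))
  expect_equal(anti_inflammatory_onset(ramp, q = 0.5), 5.0)

  flat <- as_trajectory(data.frame(time_h = 0:10, PI = 1, AI = 0))
  expect_true(is.na(anti_inflammatory_onset(flat)))

  # fine-grid oracle on the demo trajectory
  tr <- demo_trajectory(72, 0.1)
  fine <- demo_trajectory(72, 0.001)
  t_coarse <- anti_inflammatory_onset(tr, q = 0.1)
  thr <- 0.1 * max(fine$states$AI)
  t_brute <- fine$states$time_h[which(fine$states$AI >= thr)[1L]]
  expect_lt(abs(t_coarse - t_brute), 0.01)
})

test_that("single-parameter fits recover truth and degenerate data is flagged", {
  tg <- seq(0, 72, length.out = 60)
  tr <- integrate_clock(demo_params(), demo_path(), c(t = 0, PI = 0, AI = 0),
                        tg)
  guess <- demo_params()
  guess$dpp <- 0.9
  fit <- fit_parameters(tr$states, demo_path(),
                        do.call(clock_params, unclass(guess)),
                        fixed = setdiff(names(unclass(guess)), "dpp"),
                        n_starts = 2)
  expect_lt(abs(fit$params$dpp - 0.45) / 0.45, 1e-3)
  expect_false(fit$non_identifiable)

  zero_obs <- data.frame(time_h = 0:20, PI = 0, AI = 0)
  fit0 <- fit_parameters(zero_obs, pathogen_load("constant", value = 0),
                         demo_params())
  expect_true(fit0$non_identifiable)
  expect_equal(fit0$rss, 0)
  expect_identical(unclass(fit0$params), unclass(demo_params()))
})

test_that("pathogen-load inputs respect their declared shapes", {
  pl <- demo_path()
  t <- seq(0, 100, by = 0.5)
  v <- path_value(pl, t)
  expect_true(all(v >= 0))
  # clearance switches on at t_clear: decreasing beyond the peak
  expect_lt(v[t == 80], v[t == 30])
  # sampled series interpolates linearly and holds ends
  ps <- pathogen_load("sampled",
                      series = data.frame(time_h = c(0, 10), value = c(0, 2)))
  expect_equal(path_value(ps, c(0, 5, 10, 20)), c(0, 1, 2, 2))
  expect_error(pathogen_load("sampled",
    series = data.frame(time_h = c(0, 0), value = c(1, 1))), "increasing")
})
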