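test_that("imbalance cost is the L1 distance from the setpoint", {
  sp <- physio_setpoint(1, 1)
  expect_equal(imbalance_cost(1, 1, sp), 0)
  expect_equal(imbalance_cost(3, 1, sp), 2)
  expect_equal(imbalance_cost(3, 0.5, sp), 2.5)
  sp2 <- physio_setpoint(2, 0.5)
  expect_equal(imbalance_cost(0, 0, sp2), 2.5)
})

test_that("burden kinds follow their declared shapes inside the window", {
  cfg_c <- cost_config(burden_kind = "constant", t0 = 0, t1 = 72)
  expect_equal(burden(c(0, 36, 72), cfg_c), c(1, 1, 1))
  cfg_l <- cost_config(burden_kind = "linear_increasing", t0 = 0, t1 = 72)
  expect_equal(burden(c(0, 36, 72), cfg_l), c(0, 0.5, 1))
  cfg_u <- cost_config(burden_kind = "user_table", t0 = 0, t1 = 10,
                       burden_table = data.frame(time_h = c(0, 10),
                                                 burden = c(2, 4)))
  expect_equal(burden(5, cfg_u), 3)
  expect_error(burden(80, cfg_l), "outside")
})

test_that("pointwise objective decomposes into cost plus weighted burden", {
  tr <- as_trajectory(data.frame(time_h = seq(0, 72, by = 0.5),
                                 PI = 1 + abs(seq(0, 72, by = 0.5) - 36) / 10,
                                 AI = 1))
  sp <- physio_setpoint(1, 1)
  cfg0 <- cost_config(lambda_weight = 0, setpoint = sp, t0 = 0, t1 = 72)
  probes <- c(0, 7.25, 18, 36, 53.1, 70, 72)
  st <- list(PI = 1 + abs(probes - 36) / 10, AI = rep(1, length(probes)))
  expect_equal(objective(probes, tr, cfg0),
               imbalance_cost(st$PI, st$AI, sp))

  cfg <- cost_config(lambda_weight = 0.5, setpoint = sp,
                     burden_kind = "linear_increasing", t0 = 0, t1 = 72)
  expect_equal(objective(probes, tr, cfg),
               abs(probes - 36) / 10 + 0.5 * probes / 72)

  # constant trajectory at setpoint: objective reduces to lambda * burden
  flat <- as_trajectory(data.frame(time_h = 0:72, PI = 1, AI = 1))
  cfg_flat <- cost_config(lambda_weight = 0.4, setpoint = sp,
                          burden_kind = "constant", t0 = 0, t1 = 72)
  expect_equal(objective(c(3, 40), flat, cfg_flat), c(0.4, 0.4))
})

test_that("optimal_time honours tie-breaking and monotone objectives", {
  sp <- physio_setpoint(1, 1)
  flat <- as_trajectory(data.frame(time_h = 0:72, PI = 1, AI = 1))
  cfg <- cost_config(lambda_weight = 0.4, setpoint = sp,
                     burden_kind = "constant", t0 = 0, t1 = 72)
  res <- optimal_time(flat, cfg)
  expect_equal(res$t_star, 0)  # earliest tie
  expect_equal(nrow(res$windows), 1L)
  expect_equal(unlist(res$windows[1, ]), c(lo = 0, hi = 72))

  cfg_mono <- cost_config(lambda_weight = 0.7, setpoint = sp,
                          burden_kind = "linear_increasing", t0 = 0, t1 = 72)
  expect_equal(optimal_time(flat, cfg_mono)$t_star, 0)
})

test_that("optimiser matches an exhaustive fine scan on randomised scenarios", {
  set.seed(101)
  for (i in 1:50) {
    # random unimodal-ish imbalance profiles around a moving trough
    t <- seq(0, 72, by = 0.5)
    trough <- runif(1, 5, 67)
    scalef <- runif(1, 0.05, 0.5)
    pi_t <- 1 + scalef * abs(t - trough)^runif(1, 0.8, 1.6)
    ai_t <- 1 + 0.3 * sin(t / runif(1, 3, 9))^2
    tr <- as_trajectory(data.frame(time_h = t, PI = pi_t, AI = ai_t))
    cfg <- cost_config(lambda_weight = runif(1), setpoint = physio_setpoint(),
                       burden_kind = sample(c("constant",
                                              "linear_increasing"), 1),
                       t0 = 0, t1 = 72)
    res <- optimal_time(tr, cfg, grid_resolution = 0.1)
    fine <- seq(0, 72, by = 0.001)
    vals <- objective(fine, tr, cfg)
    t_brute <- fine[which(vals <= min(vals) + 1e-12)[1L]]
    expect_lt(abs(res$t_star - t_brute), 0.1 + 1e-9)
  }
})

test_that("near-optimal windows are consistent with the epsilon criterion", {
  t <- seq(0, 72, by = 0.5)
  tr <- as_trajectory(data.frame(time_h = t,
                                 PI = 1 + 0.2 * (abs(t - 20) %/% 10), AI = 1))
  cfg <- cost_config(lambda_weight = 0, setpoint = physio_setpoint(),
                     t0 = 0, t1 = 72)
  res <- optimal_time(tr, cfg, grid_resolution = 0.1)
  grid <- seq(0, 72, by = 0.1)
  vals <- objective(grid, tr, cfg)
  near <- vals <= min(vals) + res$epsilon + 1e-12
  in_window <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(res$windows)))
    in_window <- in_window |
      (grid >= res$windows$lo[i] - 1e-9 & grid <= res$windows$hi[i] + 1e-9)
  # every near-optimal grid point is inside a window and vice versa
  expect_true(all(in_window[near]))
  expect_true(all(vals[in_window] <= min(vals) + res$epsilon + 1e-12))
  # window endpoints themselves qualify
  for (i in seq_len(nrow(res$windows))) {
    expect_lte(objective(res$windows$lo[i], tr, cfg),
               min(vals) + res$epsilon + 1e-12)
    expect_lte(objective(res$windows$hi[i], tr, cfg),
               min(vals) + res$epsilon + 1e-12)
  }
})

test_that("interventions modulate parameters only inside their window", {
  p <- demo_params()
  ident <- intervention_spec("identity", start = 0, duration = 24,
                             multipliers = c(kpi = 1, kpp = 1))
  for (t in c(0, 10, 30)) {
    expect_identical(unclass(params_at_time(p, ident, t)), unclass(p))
  }
  kill_kpi <- intervention_spec("no_forcing", start = 6, duration = 12,
                                multipliers = c(kpi = 0))
  inside <- params_at_time(p, kill_kpi, 10)
  expect_equal(inside$kpi, 0)
  # with kpi = 0, dPI/dt loses the pathogen-forcing term exactly
  d <- clock_derivatives(10, 2, 1, inside, pathogen_load("constant", 5))
  d_expected <- p$kpp * 2 * hill_activation(2, p$theta_pi, p$n_hill) -
    p$dpp * 2
  expect_equal(unname(d["dPI"]), d_expected)
  outside <- params_at_time(p, kill_kpi, 18)  # window is [6, 18)
  expect_equal(outside$kpi, p$kpi)
  expect_error(intervention_spec("mystery_drug"), "unknown preset")
})

test_that("innate blockade lowers integrated PI exposure in paired runs", {
  tg <- seq(0, 72, by = 0.1)
  base <- integrate_clock(demo_params(), demo_path(),
                          c(t = 0, PI = 0, AI = 0), tg)
  blocked <- integrate_clock(demo_params(), demo_path(),
                             c(t = 0, PI = 0, AI = 0), tg,
                             modulation = intervention_spec(
                               "myd88_blockade", start = 6, duration = 48))
  expect_lt(pi_exposure(blocked), pi_exposure(base))

  # monotone response: stronger kpi reduction never increases exposure
  set.seed(7)
  for (i in 1:5) {
    f_strong <- runif(1, 0, 0.5)
    f_weak <- f_strong + runif(1, 0, 0.5)
    run <- function(f) pi_exposure(integrate_clock(
      demo_params(), demo_path(), c(t = 0, PI = 0, AI = 0), tg,
      modulation = intervention_spec("x", start = 6, duration = 24,
                                     multipliers = c(kpi = f))))
    expect_lte(run(f_strong), run(f_weak) + 1e-8)
  }
})

test_that("counterfactual objective scores the aftermath of intervening", {
  tg <- seq(0, 72, by = 0.25)
  tr <- integrate_clock(demo_params(), demo_path(),
                        c(t = 0, PI = 0, AI = 0), tg)
  cfg <- cost_config(lambda_weight = 0, setpoint = physio_setpoint(),
                     t0 = 0, t1 = 48, mode = "counterfactual")
  spec <- intervention_spec("myd88_blockade", duration = 24)
  expect_error(objective(10, tr, cfg), "intervention")
  # direct recomputation at one probe time
  tt <- 12
  o <- objective(tt, tr, cfg, intervention = spec)
  spec_t <- spec
  spec_t$start <- tt
  sub <- tg[tg >= tt]
  st0 <- list(PI = approx(tg, tr$states$PI, tt)$y,
              AI = approx(tg, tr$states$AI, tt)$y)
  ctr <- integrate_clock(demo_params(), demo_path(),
                         c(t = tt, PI = st0$PI, AI = st0$AI), sub,
                         modulation = spec_t)
  expect_equal(o, mean(imbalance_cost(ctr$states$PI, ctr$states$AI,
                                      physio_setpoint())))
  # intervening early beats the uncontrolled pointwise cost at the peak
  expect_lt(o, max(imbalance_cost(tr$states$PI, tr$states$AI,
                                  physio_setpoint())))
})
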