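# Shared fixtures: the demo parameter regime used across tests.
demo_params <- function() {
  clock_params(kpi = 0.8, kpp = 0.3, dpp = 0.45,
               kai = 0.1, kap = 0.35, dai = 0.2,
               theta_pi = 1.2, theta_ai = 1.5, n_hill = 2)
}

demo_path <- function() {
  pathogen_load("logistic_with_clearance", P0 = 0.05, g = 0.4, K = 3,
                t_clear = 20, c_clear = 0.15)
}

demo_trajectory <- function(t1 = 100, by = 0.1) {
  integrate_clock(demo_params(), demo_path(), c(t = 0, PI = 0, AI = 0),
                  seq(0, t1, by = by))
}

# wrap a bare states data.frame as a trajectory (for hand-built scenarios)
as_trajectory <- function(states, params = NULL, path = NULL) {
  structure(list(states = states, params_used = params, path_used = path,
                 n_clamped = 0L),
            class = "clock_trajectory")
}
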