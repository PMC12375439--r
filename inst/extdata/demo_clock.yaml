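# Demonstration parameter set for the PI/AI immune clock.
# Bounded regime: kpp < dpp, so Hill-gated self-amplification can only
# transiently amplify, never diverge. Units: rates 1/h, thresholds in
# arbitrary concentration units, time in hours.
kpi: 0.8
kpp: 0.3
dpp: 0.45
kai: 0.1
kap: 0.35
dai: 0.2
theta_pi: 1.2
theta_ai: 1.5
n_hill: 2
path:
  kind: logistic_with_clearance
  P0: 0.05
  g: 0.4
  K: 3
  t_clear: 20
  c_clear: 0.15
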