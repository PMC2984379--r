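synth:
  start_year: 2007.0
  end_year: 2050.0
  d_first: 0.009
  d_last: 0.0078
  migration: 1000000.0
  incidence_years: 28.0
  rho: 0.018
  lam0: -1.54
  lam1: 0.0454
  phi: 0.6
  sigma: 0.0002
  se_scale: 0.0042
  theta1: 0.0535
  theta2: 0.0765
prior:
  q_low: 0.0078
  q_high: 0.025
  mass: 0.95
mcmc:
  chains: 4.0
  warmup: 10000.0
  iter: 10000.0
  error_structure: ar1
calibration:
  i29: 0.0084
  I29: 0.0106
  lambda_high: 0.0287
  p28: 0.257
  q: 0.93
  coverage: 0.5
  efficacy: 0.5
  frac_within: 0.95
  horizon: 7.0
  eta: ~
  undiag_alloc_a: 0.398
  undiag_alloc_b: 0.129
risks:
  low:
  - 1.77
  - 2.11
  high:
  - 1.0
  - 4.08
strata:
  p: ~
  c: ~
  q: ~
intervention:
  nu: ~
  regression_rate: 0.0
output:
  scenarios:
  - low
  - middle
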