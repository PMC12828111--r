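# Default trial design configuration (mirrors design_config()).
doses: [0.1, 0.5, 0.9]
schedules: 3
n_max: 120
cohort_size: 3
prevalence: 0.5
phi_T: 0.3
phi_E: 0.3
c_i: 0.05
c_t: 0.2
c_e: 0.2
rand_floor: 0.01
variant: proposed
weights:
  w1: 0.5
  w2: 0.3
  w3: 1.2
  phi_T: 0.3
  penalty: fixed
hyper:
  zeta0: -2.2
  tau_sq: 1.0
  sigma_e0_sq: 0.3
  sigma_e1_sq: 0.3
prior:
  alpha_hat: 20
  r_hat: 1.5
  m_mu: 30
  sd_inflation: 3
mcmc:
  n_burn: 1000
  n_keep: 2000
  thin: 1
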