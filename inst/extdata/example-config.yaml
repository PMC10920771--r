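# Example run configuration.  Any key left out falls back to the package
# defaults (the emulated 4-session + transfer design with 220 trials per
# session and desk-scale MCMC settings); unknown keys are rejected.
design:
  n_training_sessions: 4
  has_transfer: true
  difficulties: [0, 0.31, 0.56, 1, 1.77, 3.16]
  trials_per_signed_level: 20
  response_window: 1.0
truth:
  rho: 0.3          # fraction of the drift-rate gain that is effector-specific
  delta_t: 0.14     # transfer non-decision time drop (s)
model: v(ses*diff)_a(ses)_t(ses)_z(ses)
mcmc:
  chains: 4
  samples: 3000
  burnin: 1000
  thin: 1
seed: 1
log_level: info
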