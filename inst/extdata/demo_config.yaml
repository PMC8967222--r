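# Demonstration pipeline: simulate fast-acquisition two-state data,
# classify diffusive states, and run the slow-channel residence analysis.
# Run with:  run_pipeline(read_run_config("demo_config.yaml"))
seed: 3
out_dir: tidysmt_demo_output
stages: [simulate, states, dwell, report]
simulate:
  protocol: fast
  n_frames: 21
  n_tracks: 500
  localization_sigma_um: 0.03
  states:
    - label: bound
      diffusivity_um2_s: 0.005
      mean_dwell_s: .inf
    - label: free
      diffusivity_um2_s: 0.5
      mean_dwell_s: .inf
  initial_weights: [0.35, 0.65]
states:
  k_range: [1, 2, 3]
  bound_D_max: 0.03
  min_population: 0.05
  posterior_threshold: 0.6
dwell:
  protocol: slow
  n_tracks: 1500
  control_n_tracks: 1500
  residence:
    type: power_law
    alpha: 2.0
    t_min_s: 0.2
  bleach:
    amplitudes: [0.5, 0.3, 0.2]
    timescales_s: [0.5, 2.0, 10.0]
  bound_radius_um: 0.2
  min_bound_frames: 2
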