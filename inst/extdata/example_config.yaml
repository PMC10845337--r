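study:
  n_segments: 8
  min_separation: 3
  n_options: 5
  repeat_fraction: 1.0
  layouts:
  - circular
  - half_matrix
  - matrix
  rng_seed: 1
  animation:
    rocking_amplitude_deg: 3.0
    n_frames: 136.0
    cycle_seconds: 3.0
preset: expert
rt_cutoff: 5000.0
consistency_threshold: 0.2
alpha: 0.05
adjust_method: bh
output_dir: layoutstudy_output
seed: 1
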