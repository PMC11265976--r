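# Desk-scale demo: a small synthetic antennal lobe (3 glomeruli, 4 planes)
# run through stabilization, response maps, ROI calls and traces, plus a
# synthetic colony bioassay compared between age cohorts. All frame windows
# are 1-based and default to the quantification conventions (baseline 1-5,
# peak 9-14, AUC 6-40, threshold 0.2, clip [-1, 4], min-filter radius 2).
seed: 42
imaging:
  scene:
    volume_shape: [45, 4, 48, 48]
    n_glomeruli: 3
    glomerulus_radius_vox: 6
    baseline_intensity: 1000
    background_intensity: 100
    noise_sd: 5
    motion_sd_px: 0.6
    rise_tau_s: 1
    decay_tau_s: 5
  stimulus:
    trigger_frame: 3
    delay_s: 3
    duration_s: 5
  tuning:
    odorants: ["4-methyl-3-heptanone", "4-methyl-3-heptanol", "paraffin oil"]
    amplitudes:            # rows = glomeruli, columns = odorants above
      - [1.2, 0.1, 0.0]
      - [0.8, 0.9, 0.0]
      - [0.0, 0.5, 0.0]
  manifest:
    concentration_pct: 48
    n_repeats: 3
  threshold: 0.2
  artifact_threshold_px: 5
behavior:
  scenario:
    n_young: 12
    n_old: 12
    nest_radius_cm: 0.25
    body_radius_cm: 0.15
    arena_radius_cm: 3
    sample_interval_s: 1
    duration_s: 570
  stimulus_time_s: 270
  nest_radius_cm: 0.25
  body_radius_cm: 0.15
  model_family: logistic_growth
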