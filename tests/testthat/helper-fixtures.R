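# Noise-free scene whose sustained kinetics plateau across the peak window
# (odor arrives before frame 9 and the response does not decay), so the
# programmed amplitude equals the expected peak fold change exactly.
plateau_scene <- function(..., seed = 1) {
  scene_config(noise_sd = 0, motion_sd_px = 0,
               rise_tau_s = 0.3, decay_tau_s = Inf, seed = seed, ...)
}

tiny_tracks <- function(df) {
  # expand shorthand rows (one per ant x time) into the tracking layout
  tibble::as_tibble(df)
}
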