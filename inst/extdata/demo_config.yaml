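# Demonstration pipeline configuration (small, seconds to run).
seed: 17
simulate:
  oocyte_radius: 15
  zona_thickness: 5
  n_tzp: 24
  noise_sd: 6
  image_shape: [512, 512]
count:
  smooth_window: 3
cells:
  n_cells: 2
  threshold: 50
  min_volume: 100
frap:
  k: 0.03
  bleach_fraction: 0.8
  noise_sd: 0.5
group:
  n_per_group: 12
  effect_tzp_count: -0.35
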