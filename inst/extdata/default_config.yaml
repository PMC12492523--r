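# angionet pipeline configuration (all values shown are the defaults)
preprocess:
  gaussian_sigma: 1.0      # px
  min_object_size: 64      # px; components strictly smaller are removed
  # invert_foreground: false   # uncomment to force bright-side foreground
metrics:
  tortuosity_sample_pairs: 100
  rng_seed: 1
  weighted_paths: true
radial:
  delta_r: 50              # annulus width, px
  n_zones: 6
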