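# Packaged fixture: simulation parameters estimated from real semen
# sample 1 (segmentation/localization benchmark conditions).
# noise_variance_normalized is on the [0,1] intensity scale and is
# converted to 0-255 gray units (x 255^2) when the config is built.
frame_size: 250
n_cells: 10
n_immotile: 3
mode_probs:
  linear: 0.5
  circular: 0.5
head_radius_major: 2.86   # px, sperm head major axis
head_radius_minor: 1.86   # px, sperm head minor axis
background: 204           # gray level (80% of 255)
noise_variance_normalized: 8.22e-6
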