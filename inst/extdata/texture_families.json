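{
  "bathtub": {"family": "checkerboard", "hue": 0.5},
  "bear": {"family": "blob_noise", "hue": 0.1},
  "bird": {"family": "diagonal_stripes", "hue": 0.3},
  "butterfly": {"family": "polka_dots", "hue": 0.8},
  "elephant": {"family": "wrinkle_noise", "hue": 0.0},
  "fish": {"family": "horizontal_stripes", "hue": 0.6},
  "helmet": {"family": "smooth_grating", "hue": 0.2},
  "mailbox": {"family": "vertical_stripes", "hue": 0.7},
  "mug": {"family": "weave", "hue": 0.4},
  "phone": {"family": "zigzag", "hue": 0.9}
}
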