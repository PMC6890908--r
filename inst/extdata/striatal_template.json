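{
  "name": "datspect-striatal-template",
  "version": 2,
  "grid_shape": [
    128,
    128,
    48
  ],
  "voxel_mm": 4.4,
  "brain": {
    "center_mm": [
      0,
      0,
      0
    ],
    "semi_axes_mm": [
      70,
      90,
      60
    ],
    "reference_margin_mm": 18
  },
  "occipital": {
    "center_mm": [
      0,
      -52,
      -5
    ],
    "semi_axes_mm": [
      34,
      20,
      22
    ]
  },
  "striatum": {
    "caudate": {
      "center_mm": [
        19,
        14,
        7
      ],
      "semi_axes_mm": [
        8.4,
        14.7,
        11.55
      ]
    },
    "anterior_putamen": {
      "center_mm": [
        28,
        8,
        0
      ],
      "semi_axes_mm": [
        9.45,
        11.55,
        11.55
      ]
    },
    "posterior_putamen": {
      "center_mm": [
        29,
        -10,
        -1
      ],
      "semi_axes_mm": [
        9.45,
        12.6,
        11.55
      ]
    }
  },
  "pentagon": {
    "dilation_mm": 12,
    "apex_extension_frac": 0.45,
    "z_margin_mm": 12
  }
}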