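{
  "variables": ["Val", "Leu", "Ile", "Ala", "Gly"],
  "alpha": [1.5, 7.5, 7.6, 7.4, 8.8],
  "beta": [1.0, 1.2, 1.1, 1.2, 1.2],
  "g": [
    [0.0, -0.2, 0.0, 2.0, -1.8],
    [0.0, 0.0, 0.0, -1.3, 1.4],
    [0.0, -0.1, 0.0, -2.3, 2.5],
    [0.8, -1.7, 2.6, 0.0, -0.9],
    [2.4, -2.3, -1.9, 2.1, 0.0]
  ],
  "h": [
    [0.0, 0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.7, 0.0],
    [0.0, 0.0, 0.0, 0.0, 1.3]
  ],
  "mask_g": [
    [false, false, false, false, false],
    [false, false, false, false, false],
    [false, false, false, false, false],
    [false, false, false, false, false],
    [false, false, false, false, false]
  ],
  "mask_h": [
    [false, true, true, true, true],
    [true, false, true, true, true],
    [true, true, false, true, true],
    [true, true, true, false, true],
    [true, true, true, true, false]
  ]
}
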