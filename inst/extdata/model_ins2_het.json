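{
  "variables": ["Val", "Leu", "Ile", "Ala", "Gly"],
  "alpha": [4.4, 4.8, 3.8, 4.6, 2.8],
  "beta": [1.5, 1.0, 1.5, 1.5, 5.6],
  "g": [
    [0.0, -0.7, 0.0, 0.6, 0.1],
    [0.0, 0.0, 0.0, -1.0, 1.2],
    [0.0, -1.3, 0.0, 0.4, 0.8],
    [-0.6, 1.0, 0.9, 0.0, -1.1],
    [1.2, -1.1, -1.5, 1.7, 0.0]
  ],
  "h": [
    [0.01, 0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0, 0.8]
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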