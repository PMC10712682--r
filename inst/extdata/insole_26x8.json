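{
  "n_rows": 26,
  "n_cols": 8,
  "pitch_mm": 10,
  "active": [
    [0, 0, 1, 1, 1, 1, 0, 0],
    [0, 1, 1, 1, 1, 1, 1, 0],
    [1, 1, 1, 1, 1, 1, 1, 0],
    [1, 1, 1, 1, 1, 1, 1, 1],
    [1, 1, 1, 1, 1, 1, 1, 1],
    [1, 1, 1, 1, 1, 1, 1, 1],
    [1, 1, 1, 1, 1, 1, 1, 1],
    [1, 1, 1, 1, 1, 1, 1, 1],
    [1, 1, 1, 1, 1, 1, 1, 1],
    [1, 1, 1, 1, 1, 1, 1, 1],
    [1, 1, 1, 1, 1, 1, 1, 1],
    [1, 1, 1, 1, 1, 1, 1, 0],
    [0, 1, 1, 1, 1, 1, 1, 0],
    [0, 1, 1, 1, 1, 1, 1, 0],
    [0, 1, 1, 1, 1, 1, 1, 0],
    [0, 1, 1, 1, 1, 1, 1, 0],
    [0, 1, 1, 1, 1, 1, 1, 0],
    [1, 1, 1, 1, 1, 1, 1, 0],
    [1, 1, 1, 1, 1, 1, 1, 0],
    [1, 1, 1, 1, 1, 1, 1, 0],
    [1, 1, 1, 1, 1, 1, 1, 0],
    [1, 1, 1, 1, 1, 1, 1, 0],
    [1, 1, 1, 1, 1, 1, 1, 0],
    [0, 1, 1, 1, 1, 1, 1, 0],
    [0, 1, 1, 1, 1, 1, 0, 0],
    [0, 0, 1, 1, 1, 0, 0, 0]
  ],
  "subarea": [
    [
      "",
      "",
      "toe",
      "toe",
      "toe",
      "toe",
      "",
      ""
    ],
    [
      "",
      "toe",
      "toe",
      "toe",
      "toe",
      "toe",
      "toe",
      ""
    ],
    [
      "toe",
      "toe",
      "toe",
      "toe",
      "toe",
      "toe",
      "toe",
      ""
    ],
    [
      "toe",
      "toe",
      "toe",
      "toe",
      "toe",
      "toe",
      "toe",
      "toe"
    ],
    [
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot"
    ],
    [
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot"
    ],
    [
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot"
    ],
    [
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot"
    ],
    [
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot"
    ],
    [
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot"
    ],
    [
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot",
      "forefoot"
    ],
    [
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      ""
    ],
    [
      "",
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      ""
    ],
    [
      "",
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      ""
    ],
    [
      "",
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      ""
    ],
    [
      "",
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      ""
    ],
    [
      "",
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      ""
    ],
    [
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      "arch",
      ""
    ],
    [
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      ""
    ],
    [
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      ""
    ],
    [
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      ""
    ],
    [
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      ""
    ],
    [
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      ""
    ],
    [
      "",
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      ""
    ],
    [
      "",
      "heel",
      "heel",
      "heel",
      "heel",
      "heel",
      "",
      ""
    ],
    [
      "",
      "",
      "heel",
      "heel",
      "heel",
      "",
      "",
      ""
    ]
  ]
}
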