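{
  "states": ["O", "S", "V", "B", "D"],
  "absorbing": ["D"],
  "edges": [
    ["O", "S"],
    ["O", "V"],
    ["O", "B"],
    ["V", "S"],
    ["V", "B"],
    ["B", "S"],
    ["B", "D"],
    ["S", "D"]
  ],
  "death_rates": {
    "S": 0.00002,
    "B": 0.00001
  },
  "exponent": 2
}
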