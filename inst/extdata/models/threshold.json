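{
  "name": "threshold",
  "species": {"X": 0},
  "parameters": {"s": 10, "kd": 2},
  "rates": {"X": "s - kd*X"},
  "events": [],
  "viability": {"expression": "X >= 2", "horizon": 10},
  "gene_map": {"G1": {"synthesis": ["s"], "products": ["X"]}}
}
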