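{
  "name": "oscillator",
  "species": {"x1": 0.5, "x2": 0.5, "x3": 0.5},
  "parameters": {"a": 5, "K": 1, "h": 10, "b1": 0.4, "b2": 0.4, "b3": 0.4,
                 "c1": 0.4, "c2": 0.4, "mu": 0.07, "thr": 1.3},
  "rates": {
    "x1": "a/(1 + (x3/K)^h) - b1*x1",
    "x2": "c1*x1 - b2*x2",
    "x3": "c2*x2 - b3*x3"
  },
  "mass": {"init": 1, "rate": "mu*m"},
  "events": [
    {"name": "division", "trigger": "x3 - thr", "direction": "down",
     "assignments": {"m": "m/2"}}
  ],
  "viability": {"min_divisions": 3, "horizon": 500, "max_mass": 50},
  "gene_map": {
    "ACT1": {"synthesis": ["a"],  "products": ["x1"]},
    "MID1": {"synthesis": ["c1"], "products": ["x2"]},
    "REP1": {"synthesis": ["c2"], "products": ["x3"]}
  }
}
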