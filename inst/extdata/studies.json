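{
  "cp": {
    "trait": "CP",
    "n_total": 34615,
    "n_cases": 12289,
    "n_controls": 22326,
    "ancestry": "European"
  },
  "egfr": {
    "trait": "eGFR",
    "n_total": 439303,
    "ancestry": "European"
  },
  "bun": {
    "trait": "BUN",
    "n_total": 439303,
    "ancestry": "European"
  }
}
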