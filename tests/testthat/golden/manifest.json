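{
  "parameters": {
    "fdrThreshold": 0.05,
    "windowBp": 1000,
    "minSetSize": 2,
    "anchor": "gene",
    "skipNormalize": false
  },
  "seed": 11,
  "counts": {
    "features_in": 200,
    "features_tested": 200,
    "probes_unmapped": 0,
    "ambiguous_genes": 0,
    "de_total": 0,
    "de_up": 0,
    "de_down": 0,
    "background_with_coords": 200,
    "genes_without_coords": 0
  },
  "subunits": ["p65", "p50", "RelB", "p52"]
}
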