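{
  "title": "reefpam statistics report",
  "required": ["provenance", "alpha", "margin_db", "n_feature_rows", "ancova", "effect_calls"],
  "ancova_required": ["band", "period", "response", "terms"],
  "effect_call_required": ["band", "period", "response", "difference_db", "p", "verdict"]
}
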