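{
  "nodes": ["change", "flow", "frac_agriculture", "frac_developed", "nonpoint_N", "nonpoint_P", "tss"],
  "edges": [
    ["frac_agriculture", "nonpoint_N"],
    ["frac_agriculture", "nonpoint_P"],
    ["frac_developed", "nonpoint_N"],
    ["flow", "nonpoint_N"],
    ["flow", "nonpoint_P"],
    ["flow", "tss"],
    ["nonpoint_N", "change"],
    ["tss", "change"],
    ["flow", "change"]
  ],
  "correlated_errors": [],
  "lag_interactions": [],
  "group": "site_id",
  "order": ["frac_agriculture", "frac_developed", "flow", "point_N", "nonpoint_N", "point_P", "nonpoint_P", "tss", "change"],
  "lag_variable": "prev_cover"
}
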