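{
  "nodes": ["change", "chla", "salinity", "secchi", "temperature", "total_N"],
  "edges": [
    ["total_N", "chla"],
    ["chla", "change"],
    ["secchi", "change"],
    ["salinity", "change"],
    ["temperature", "change"]
  ],
  "correlated_errors": [],
  "lag_interactions": [],
  "group": "site_id",
  "order": ["temperature", "salinity", "secchi", "total_N", "total_P", "chla", "change"],
  "lag_variable": "prev_cover"
}
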