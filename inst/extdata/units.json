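{
  "t002": {"concentration": "ng/mL"},
  "t003": {"e_raw": "ng/mL", "e_norm": "percent of 0-100 scale",
           "threshold": "ng/mL", "h": "dimensionless", "n": "count"},
  "t005": {"e": "percent of 0-100 scale", "h": "dimensionless",
           "n": "count"},
  "t006": {"value": "see units column"}
}
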