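{
  "referent": "last",
  "model": "current_sd",
  "nri": 0.196464724282631,
  "nri_events": 0.034866092415597,
  "nri_nonevents": 0.161598631867034,
  "mean_risk_last": 0.184916122056717,
  "km_event_fraction": 0.164006839569561
}
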