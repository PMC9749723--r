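"quantity","value"
"subjects",4000
"women_pct",38.73
"entry_age_mean",59.89
"dx_age_mean",56.94
"events",806
"events_per_1000py",16.4
"followup_years_mean",12.29
"median_n_sbp",30
"median_n_tc",15
"median_n_hdl",13
"median_n_hba1c",18
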