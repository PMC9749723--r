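"sex","factor","mean_at_50","slope_per_year","residual_sd","iterations"
"M","SBP",138.151,0.3697,10.395,19
"M","TC",5.218,-0.0146,0.675,19
"M","HDL",1.246,0.0032,0.137,19
"M","HBA1C",7.575,0.0241,0.833,19
"F","SBP",138.006,0.3575,10.519,19
"F","TC",5.222,-0.0143,0.673,19
"F","HDL",1.257,0.0026,0.135,19
"F","HBA1C",7.588,0.0243,0.809,19
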