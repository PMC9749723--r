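"model","c_index","c_lo","c_hi","c_diff","c_diff_lo","c_diff_hi","brier","brier_lo","brier_hi","brier_diff","brier_diff_lo","brier_diff_hi","n","n_events","arm"
"last",0.696234284706265,0.668111860307452,0.722914751612361,0,0,0,0.159263466839442,0.147711579866233,0.170966627235193,0,0,0,12381,2146,"sbp_variability_signal"
"current_sd",0.727074982979053,0.697850750379941,0.754587783546248,0.030840698272788,0.0131465252507686,0.0468191501812443,0.151745842730796,0.141305325702222,0.163265172644834,-0.00751762410864562,-0.0110167438232264,-0.00270456558328597,12381,2146,"sbp_variability_signal"
"last",0.678485913243993,0.635690708802303,0.722419639665725,0,0,0,0.0901071486432859,0.076593005852367,0.10331063990986,0,0,0,13572,1006,"null_no_variability_effect"
"current_sd",0.681487832032201,0.638001406434793,0.72127189206445,0.0030019187882081,-0.00878099634697442,0.0121532074770255,0.0901973903660152,0.0767275305019781,0.103201706832175,9.02417227293395e-05,-0.00120466559268941,0.00145253744717422,13572,1006,"null_no_variability_effect"
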