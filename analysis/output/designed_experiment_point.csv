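"model","c_index","c_lo","c_hi","c_diff","c_diff_lo","c_diff_hi","brier","brier_lo","brier_hi","brier_diff","brier_diff_lo","brier_diff_hi","n","n_events","arm"
"last",0.696234284706265,NA,NA,0,NA,NA,0.159263466839442,NA,NA,0,NA,NA,12381,2146,"sbp_variability_signal"
"current_sd",0.727074982979053,NA,NA,0.030840698272788,NA,NA,0.151745842730796,NA,NA,-0.00751762410864562,NA,NA,12381,2146,"sbp_variability_signal"
"current_sd_sbp_only",0.727930301713972,NA,NA,0.0316960170077074,NA,NA,0.151501132875816,NA,NA,-0.00776233396362544,NA,NA,12381,2146,"sbp_variability_signal"
"current_sd_tc_only",0.695744518727602,NA,NA,-0.000489765978663126,NA,NA,0.158450251448675,NA,NA,-0.000813215390767202,NA,NA,12381,2146,"sbp_variability_signal"
"current_sd_hdl_only",0.697184095587376,NA,NA,0.000949810881111235,NA,NA,0.158438518909727,NA,NA,-0.000824947929714381,NA,NA,12381,2146,"sbp_variability_signal"
"current_sd_hba1c_only",0.696735038143787,NA,NA,0.00050075343752265,NA,NA,0.15847341632903,NA,NA,-0.000790050510411644,NA,NA,12381,2146,"sbp_variability_signal"
"last",0.678485913243993,NA,NA,0,NA,NA,0.0901071486432859,NA,NA,0,NA,NA,13572,1006,"null_no_variability_effect"
"current_sd",0.681487832032201,NA,NA,0.0030019187882081,NA,NA,0.0901973903660152,NA,NA,9.02417227293395e-05,NA,NA,13572,1006,"null_no_variability_effect"
"current_sd_sbp_only",0.676219738730174,NA,NA,-0.00226617451381839,NA,NA,0.0906512100941601,NA,NA,0.000544061450874198,NA,NA,13572,1006,"null_no_variability_effect"
"current_sd_tc_only",0.678719523603272,NA,NA,0.000233610359279379,NA,NA,0.0900990500127287,NA,NA,-8.09863055717397e-06,NA,NA,13572,1006,"null_no_variability_effect"
"current_sd_hdl_only",0.679264785584711,NA,NA,0.000778872340718273,NA,NA,0.0903130225097135,NA,NA,0.000205873866427592,NA,NA,13572,1006,"null_no_variability_effect"
"current_sd_hba1c_only",0.679008378961801,NA,NA,0.000522465717808118,NA,NA,0.0905847242171263,NA,NA,0.000477575573840414,NA,NA,13572,1006,"null_no_variability_effect"
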