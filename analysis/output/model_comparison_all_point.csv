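"model","c_index","c_lo","c_hi","c_diff","c_diff_lo","c_diff_hi","brier","brier_lo","brier_hi","brier_diff","brier_diff_lo","brier_diff_hi","n","n_events"
"last",0.682106321692019,NA,NA,0,NA,NA,0.13356819030263,NA,NA,0,NA,NA,13565,1649
"mean",0.683321843544194,NA,NA,0.00121552185217411,NA,NA,0.133594920243384,NA,NA,2.67299407531729e-05,NA,NA,13565,1649
"current",0.686606405482185,NA,NA,0.00450008379016531,NA,NA,0.132992432928826,NA,NA,-0.000575757373804248,NA,NA,13565,1649
"last_sd",0.689051874140147,NA,NA,0.00694555244812789,NA,NA,0.132384570759976,NA,NA,-0.00118361954265414,NA,NA,13565,1649
"mean_sd",0.690541595545374,NA,NA,0.00843527385335419,NA,NA,0.132397325124799,NA,NA,-0.00117086517783152,NA,NA,13565,1649
"current_sd",0.693787774563313,NA,NA,0.0116814528712933,NA,NA,0.13168692162757,NA,NA,-0.00188126867506058,NA,NA,13565,1649
"current_sd_sbp_only",0.694226983042275,NA,NA,0.0121206613502559,NA,NA,0.131032155188609,NA,NA,-0.00253603511402176,NA,NA,13565,1649
"current_sd_tc_only",0.687639984767249,NA,NA,0.00553366307522951,NA,NA,0.133021702460094,NA,NA,-0.000546487842536303,NA,NA,13565,1649
"current_sd_hdl_only",0.686290624432409,NA,NA,0.00418430274038994,NA,NA,0.133200146150141,NA,NA,-0.000368044152489394,NA,NA,13565,1649
"current_sd_hba1c_only",0.685736768930807,NA,NA,0.00363044723878791,NA,NA,0.133645383624291,NA,NA,7.71933216609511e-05,NA,NA,13565,1649
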