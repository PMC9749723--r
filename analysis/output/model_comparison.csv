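"model","c_index","c_lo","c_hi","c_diff","c_diff_lo","c_diff_hi","brier","brier_lo","brier_hi","brier_diff","brier_diff_lo","brier_diff_hi","n","n_events"
"last",0.682106321692019,0.653489654907364,0.714024892642441,0,0,0,0.13356819030263,0.120719571464782,0.144433467709355,0,0,0,13565,1649
"mean",0.683321843544194,0.655334733026563,0.717566584383582,0.00121552185217411,-0.00355417695729646,0.00779030138058851,0.133594920243384,0.121338866496328,0.144937279011775,2.67299407531729e-05,-0.00129918424402893,0.00147351688381447,13565,1649
"current",0.686606405482185,0.659188053119748,0.719759461341557,0.00450008379016531,0.000473042493167558,0.00914963917352458,0.132992432928826,0.120751368053712,0.144262531703307,-0.000575757373804248,-0.00179230424298618,0.00049151201022101,13565,1649
"last_sd",0.689051874140147,0.660857144036547,0.7210110243074,0.00694555244812789,0.000570633878340035,0.0139635898557458,0.132384570759976,0.119822235264925,0.143662778024386,-0.00118361954265414,-0.00266730270754442,0.000305190750240696,13565,1649
"mean_sd",0.690541595545374,0.661093592661388,0.726387162233891,0.00843527385335419,-0.000315376825526537,0.0184271839363668,0.132397325124799,0.120530905734835,0.144052362792945,-0.00117086517783152,-0.00354645680675441,0.00104925583321087,13565,1649
"current_sd",0.693787774563313,0.664616471365748,0.72731148700181,0.0116814528712933,0.00300027672136612,0.0208090710287836,0.13168692162757,0.120288705262458,0.14295029787072,-0.00188126867506058,-0.00370404343334363,0.000147956614883213,13565,1649
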