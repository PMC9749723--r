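{
  "sex": "M",
  "spec": {
    "cross_factor": "full",
    "max_iter": 200,
    "tol": 1e-06
  },
  "center": {
    "SBP": 142.898426106124,
    "TC": 5.01844597336126,
    "HDL": 1.28359699022038,
    "HBA1C": 7.81366078640226
  },
  "scale": {
    "SBP": 18.7644296855162,
    "TC": 1.34093389742131,
    "HDL": 0.343134405882853,
    "HBA1C": 2.09104703207201
  },
  "beta": {
    "sbp_int": -0.253015164457631,
    "sbp_age": 0.0197007866328638,
    "sbp_age2": -2.00515299884289e-05,
    "tc_int": 0.148905100232849,
    "tc_age": -0.0108568055594059,
    "tc_age2": 3.47424835439124e-06,
    "hdl_int": -0.11006662220391,
    "hdl_age": 0.0094229692701224,
    "hdl_age2": -5.77107078807446e-05,
    "hba1c_int": -0.114096277529798,
    "hba1c_age": 0.0115162941788019,
    "hba1c_age2": -2.07421945818336e-05
  },
  "G": [
    [0.541281011152302, 0.000206875562068915, 0.00167964078738699, -0.000583573677467024, 0.0100541133392883, 0.000157059381479442, 0.0123275600153489, 0.000219524216912127],
    [0.000206875562068915, 0.000241943917480609, 0.000215501840967587, -4.04439867407439e-06, 8.74037106850872e-05, -2.85234904731077e-05, -2.09822624871375e-05, -1.77080848271149e-05],
    [0.00167964078738699, 0.000215501840967587, 0.550271419223286, 0.000442506261568306, -0.0167896266353488, 0.00127794832426442, -0.0241761540472028, 0.000665406755380245],
    [-0.000583573677467024, -4.04439867407439e-06, 0.000442506261568306, 0.000485587754131808, -0.000620634971888031, -4.32214364116874e-06, 0.000262418593378727, 3.44748030385181e-05],
    [0.0100541133392883, 8.74037106850872e-05, -0.0167896266353488, -0.000620634971888031, 0.669965447127787, -0.000545627409458921, 0.0226906857320413, 9.7662365021147e-05],
    [0.000157059381479442, -2.85234904731077e-05, 0.00127794832426442, -4.32214364116874e-06, -0.000545627409458921, 0.000547632681261593, 0.00032948089012334, -7.43610353191057e-05],
    [0.0123275600153489, -2.09822624871375e-05, -0.0241761540472028, 0.000262418593378727, 0.0226906857320413, 0.00032948089012334, 0.533261527455121, -1.41722251778893e-05],
    [0.000219524216912127, -1.77080848271149e-05, 0.000665406755380245, 3.44748030385181e-05, 9.7662365021147e-05, -7.43610353191057e-05, -1.41722251778893e-05, 0.000827008034717939]
  ],
  "sigma2": {
    "SBP": 0.306872617462893,
    "TC": 0.253696335950842,
    "HDL": 0.159710441548885,
    "HBA1C": 0.158613081135138
  },
  "loglik": -105644.276566004,
  "iterations": 19,
  "converged": true,
  "ridged": false
}
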