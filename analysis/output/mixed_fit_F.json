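{
  "sex": "F",
  "spec": {
    "cross_factor": "full",
    "max_iter": 200,
    "tol": 1e-06
  },
  "center": {
    "SBP": 142.86386114601,
    "TC": 4.94133625412792,
    "HDL": 1.29090782002574,
    "HBA1C": 7.94885424907147
  },
  "scale": {
    "SBP": 18.4286939827838,
    "TC": 1.34171635980147,
    "HDL": 0.339534687373077,
    "HBA1C": 2.03124717351465
  },
  "beta": {
    "sbp_int": -0.263588631723348,
    "sbp_age": 0.0193984935322706,
    "sbp_age2": -1.97486015977492e-05,
    "tc_int": 0.209339676937001,
    "tc_age": -0.0106414805727729,
    "tc_age2": -5.33737262111528e-05,
    "hdl_int": -0.0990899204990261,
    "hdl_age": 0.00778437495421328,
    "hdl_age2": -5.27468418917654e-05,
    "hba1c_int": -0.177513921391648,
    "hba1c_age": 0.0119853111025288,
    "hba1c_age2": -9.35671748556517e-06
  },
  "G": [
    [0.578467429469067, -0.00124573911777586, -0.0124559112232236, 0.00045358464831763, 0.0215550281690417, 2.06724144036609e-05, 0.0266464785248754, -0.000158707482620755],
    [-0.00124573911777586, 0.000237767780370371, 0.0010209555586189, 5.94060602766583e-06, -0.000254772643990938, 1.53800774309682e-05, 5.46171999217108e-05, -2.20845542036913e-06],
    [-0.0124559112232236, 0.0010209555586189, 0.540048703645432, -0.00111304310751339, -0.0282860853458604, 0.000793034240668557, 0.0303817004558841, -0.000649710536959687],
    [0.00045358464831763, 5.94060602766583e-06, -0.00111304310751339, 0.000627611984135117, 0.0007212053372685, 7.22832519677467e-06, 0.000598177616508079, 1.9046473217485e-05],
    [0.0215550281690417, -0.000254772643990938, -0.0282860853458604, 0.0007212053372685, 0.608612769350157, 0.000179848181105599, 0.0133699489875865, 0.00120056275057836],
    [2.06724144036609e-05, 1.53800774309682e-05, 0.000793034240668557, 7.22832519677467e-06, 0.000179848181105599, 0.000550390157262114, 0.000280066091726508, -2.06825810637153e-05],
    [0.0266464785248754, 5.46171999217108e-05, 0.0303817004558841, 0.000598177616508079, 0.0133699489875865, 0.000280066091726508, 0.574408546192892, 0.000511154911193791],
    [-0.000158707482620755, -2.20845542036913e-06, -0.000649710536959687, 1.9046473217485e-05, 0.00120056275057836, -2.06825810637153e-05, 0.000511154911193791, 0.000775621701168059]
  ],
  "sigma2": {
    "SBP": 0.325798320189982,
    "TC": 0.251778885633256,
    "HDL": 0.159214446814,
    "HBA1C": 0.158804912112586
  },
  "loglik": -65247.3862819377,
  "iterations": 19,
  "converged": true,
  "ridged": false
}
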