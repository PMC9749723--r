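"age_lo","age_hi","n","events","slope","reason"
41,48,870,24,0.492442894920538,NA
49,52,962,21,-0.450152442354209,NA
53,55,897,31,-0.689727775318857,NA
56,57,644,36,0.422974202046918,NA
58,58,332,28,0.582386633427156,NA
59,59,337,29,0.691422599391841,NA
60,60,341,30,0.340667472780059,NA
61,61,349,34,0.633449622790805,NA
62,62,366,39,0.71086241259389,NA
63,63,363,42,0.697382218259645,NA
64,64,355,41,0.730444163887375,NA
65,65,353,39,0.912154187624496,NA
66,66,356,39,0.601785675060834,NA
67,67,351,39,0.567908523991609,NA
68,68,361,45,0.707482453706919,NA
69,69,370,51,0.478756410221215,NA
70,70,381,46,0.647758666990886,NA
71,71,375,45,0.70804399622391,NA
72,72,388,51,0.621260255725359,NA
73,73,379,54,0.793532285295214,NA
74,74,399,62,0.953351366103911,NA
75,75,398,61,0.589909010606346,NA
76,76,392,65,0.779464405296633,NA
77,77,391,72,0.719059293571988,NA
78,78,388,76,0.558111654959828,NA
79,79,390,78,0.512518233744998,NA
80,80,402,84,0.563721771191247,NA
81,81,386,84,0.520848308045925,NA
82,82,357,79,0.453361080317377,NA
83,83,332,78,0.420196151992099,NA
84,84,309,74,0.237598691871309,NA
85,85,291,72,0.398638414704087,NA
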