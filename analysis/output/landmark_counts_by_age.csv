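"landmark_age","records","events"
41,49,0
42,86,1
43,124,3
44,182,3
45,221,5
46,276,6
47,309,8
48,346,10
49,385,12
50,427,15
51,454,22
52,492,24
53,512,28
54,540,28
55,576,32
56,602,38
57,629,37
58,647,39
59,658,43
60,679,48
61,688,51
62,714,59
63,733,62
64,742,62
65,754,74
66,761,78
67,767,85
68,774,97
69,770,103
70,773,117
71,785,119
72,797,132
73,799,143
74,810,154
75,797,158
76,803,169
77,819,175
78,827,183
79,838,202
80,806,199
81,745,183
82,684,182
83,643,187
84,581,172
85,516,152
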