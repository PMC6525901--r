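beds,discharges,bor
68,2011,0.972
78,2301,0.97
88,2585,0.966
98,2865,0.961
108,3145,0.957
113,3201,0.931
118,3216,0.896
128,3246,0.834
138,3276,0.78
148,3299,0.733
158,3306,0.688
168,3306,0.647
178,3306,0.611
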