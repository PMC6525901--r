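beds,discharges,bor
30,995,0.972
35,1153,0.97
36,1189,0.968
39,1225,0.93
38,1165,0.903
40,1258,0.922
45,1246,0.809
47,1230,0.774
50,1246,0.7305
52,1252,0.706
54,1274,0.689
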