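beds,discharges,bor
57,2279,0.986
62,2474,0.984
72,2864,0.981
82,3254,0.978
95,3756,0.974
100,3931,0.969
105,4106,0.964
110,4281,0.96
115,4438,0.951
120,4516,0.928
125,4538,0.895
130,4538,0.861
140,4538,0.8
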