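beds,discharges,bor
92,3266,0.973
110,3896,0.97
123,4351,0.969
135,4771,0.968
148,5226,0.967
160,5646,0.9668
172,5926,0.944
180,5982,0.911
185,5984,0.886
198,5984,0.828
210,5984,0.781
223,5984,0.735
236,5984,0.695
250,5984,0.656
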