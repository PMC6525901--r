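beds,discharges,bor
114,8196,0.985
130,9332,0.983
145,10345,0.977
149,10482,0.9637
152,10527,0.949
160,10640,0.911
168,10674,0.87
175,10681,0.836
182,10688,0.804
190,10696,0.771
205,10711,0.716
220,10726,0.668
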