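sample,rep1,rep2,rep3
LD8,20.6694,18.8806,8.8278
TD1,14.9900,11.7225,13.7664
TD2,33.1795,46.4623,33.7355
DPG4,109.7046,78.9029,114.8296
Dil1,2.14933,3.51072,3.70429
Dil2,3.687285,2.287295,1.714177
Dil3,3.718888,6.004963,6.049773
Dil4,4.626611,3.227553,3.434326
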