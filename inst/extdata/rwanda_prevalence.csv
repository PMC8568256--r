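state,prevalence
O,0.763882
S,0.028
V,0.175
B,0.033
D,0
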