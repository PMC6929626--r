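mn_mM,r1_s_inv
0,0.412
0.025,0.561
0.05,0.718
0.1,1.034
0.2,1.652
0.4,2.895
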