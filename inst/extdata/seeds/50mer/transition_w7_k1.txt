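# transition seed, weight 7, 50mer
1*1@11**1@*11
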