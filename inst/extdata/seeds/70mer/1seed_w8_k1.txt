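# spaced seed, weight 8, 70mer
11**1**1*1**111
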