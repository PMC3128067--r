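# 2 spaced seeds, weight 11, 70mer
1111*1*1**1*11**11
1*1**11*11***11111
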