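# 4 spaced seeds, weight 16, 70mer
1111*11*1*1*1111*11*11
111*1*11*1111**1*11111
11*11**1111**11111*111
1111111*1**11*111**111
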