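# 4 spaced seeds, weight 18, 70mer
11111111*111*11*1*1111
1111**1*11*11111111111
111*11*111111**1111111
111111111*1*111*111*11
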