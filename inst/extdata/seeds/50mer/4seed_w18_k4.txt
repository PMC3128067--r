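# 4 spaced seeds, weight 18, 50mer
111*11111*1*111*111111
1111*111*1111*11111*11
11111*1*11*111111*1111
111111*111111**1*11111
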