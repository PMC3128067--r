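# 2 spaced seeds, weight 18, 50mer
11111*1*11*1111111*111
111*11111111**1*111111
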