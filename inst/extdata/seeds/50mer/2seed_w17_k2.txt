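# 2 spaced seeds, weight 17, 50mer
11*11*1111*111*1*11111
111111*1**111*1111*111
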