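# 4 spaced seeds, weight 20, 50mer
11111111111*1*11111111
111*11111111111*111111
1111111*111111111*1111
11111*111*111111111111
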