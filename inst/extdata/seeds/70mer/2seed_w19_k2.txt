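# 2 spaced seeds, weight 19, 70mer
11111*11*1111*11111111
11111111111*111*1*1111
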