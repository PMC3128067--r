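# 4 spaced seeds, weight 20, 70mer
111111*11111111111*111
111111111*1*1111111111
1111111111111*11*11111
1111*111*1111111111111
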