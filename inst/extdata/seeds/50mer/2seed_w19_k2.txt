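# 2 spaced seeds, weight 19, 50mer
111*11111111*1*1111111
111111*11*111111*11111
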