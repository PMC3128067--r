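# 2 spaced seeds, weight 15, 50mer
111**11*1*11111*1**111
111111*1*11***1*11*111
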