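# 2 spaced seeds, weight 18, 70mer
111111*111*1**11111111
111*1111*1111111*1*111
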