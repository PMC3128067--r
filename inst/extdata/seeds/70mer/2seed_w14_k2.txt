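# 2 spaced seeds, weight 14, 70mer
11111*111***1*1*11*11
111*1**1*111**111*111
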