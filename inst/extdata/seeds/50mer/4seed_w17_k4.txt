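# 4 spaced seeds, weight 17, 50mer
11*111*111111*1*1*1111
1111*111*1111**111*111
111111111***11*11*1111
111*1**1*11*1111111111
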