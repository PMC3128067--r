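# 4 spaced seeds, weight 15, 70mer
11111*111***11*1*1*111
1111****11111*11*11*11
111*1111*11**1**111*11
11*11*1*1*11*11*1*1111
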