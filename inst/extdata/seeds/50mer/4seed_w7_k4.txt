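# 4 spaced seeds, weight 7, 50mer
11*1***1*1**11
11***11***1*11
1*111*****11*1
1*1**1*1*11**1
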