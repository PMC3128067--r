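# 8 spaced seeds, weight 10, 70mer
1*11**1***1*11111
111*111****11*1*1
1111*1**1*1*1**11
111*1***11**11*11
1*1*11*1*11**1*11
11***1111**1*1*11
11*111***1**111*1
11*1**11*11***111
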