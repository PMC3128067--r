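# 2 spaced seeds, weight 7, 70mer
111*1****11**1
11*1**11***1*1
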