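# spaced seed, weight 11, 70mer
111*1*1**11*1**111
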