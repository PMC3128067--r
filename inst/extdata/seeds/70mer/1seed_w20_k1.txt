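# spaced seed, weight 20, 70mer
1111111*111111*1111111
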