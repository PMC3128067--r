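# transition seed, weight 19, 50mer
11111@111*1111111@1111
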