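# transition seed, weight 15, 50mer
1111@11*11*111**111@1
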