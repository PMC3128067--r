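# transition seed, weight 16, 70mer
1111@1*111*1*11*111@11
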