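# transition seed, weight 11, 50mer
11*1*111@@*11*111
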