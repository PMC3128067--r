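# transition seed, weight 14, 50mer
1111*11@*11@1*1*1111
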