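1 r1 1 00 ##
1 r2 1 00 ##
1 r3 1 11 ##
1 r4 1 11 ##
1 r5 1 01 ##
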