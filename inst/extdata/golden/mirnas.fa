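>mir_a_x50
TGACCGATGTTGACCTTGGCA
>mir_b_x50
TTCAGGAGTCACGTTCAAGGT
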