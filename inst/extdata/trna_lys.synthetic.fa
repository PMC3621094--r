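>Lys1_2
GGCCCAGTCCGTGCTCCA
>Lys3
GTCCCTGTTCGGGCGCCA
>LysAlt
ATACTTCTTATGCTGCCA
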