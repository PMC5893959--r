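>tRNA-iMet_synthetic
TGGTAGCAGAGCTCGTCCA
>tRNA-Lys_synthetic
AGGTCGTGCAGTCTCACCA
>tRNA-Arg_synthetic
CGGTACGATTCACGGTCCA
>tRNA-Gly_synthetic
GTGTCCAGGTACGAGACCA
>tRNA-Asp_synthetic
TCCGTGACAGGATCGGCCA
>tRNA-Trp_synthetic
ACGGATCTGTACGCTACCA
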