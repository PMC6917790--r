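>amrA_F
GATCCTGAACGCTTAACGGC
>amrA_R
TTCGGCATGACCATTGCGAA
>blaT_F
CAGTTGCGCCTAGGTTAAGC
>blaT_R
GGAACCTTGCACGATTGCTA
>vanX_F
ACGTRGGCCATATTCGACTG
>vanX_R
TCCATGGCGTTAAGCTTGCA
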