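>linker
GTCTGCACGGTCTAGTCGACGGTATCGAGC
>primer_3p
GCGATCGTTCGACTGCCTGGAT
>primer_5p
CCATGCGTAGCTGAACTCGGTC
>l1_3p_end
TGGCGCATCGATGGTCCTAGCGTTCGGACTCATGCCGGTC
>l1_5p_end
CAGTCGGCTAGACGTCATGGCCGATTCGCTAGGTCACGTC
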