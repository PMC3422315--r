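>HTR2C_syn
ACCTTTGCGAGTAAAGAGGTGCTTATCACCATACGTAATCCTATTGCCAGGGCGGCAGAATGTGAGCTCGTTACATTCACTTTGCTGACTCTGCTGGCCCTTGGGCGCCGGTCCCTAGGTGGGTAAAAACACGCCAATAAGTACACTTCC
>GRIA2_syn
GGACTGCTACTGAGGGTCTAACAGAAATCCAAGTAGTCACCCACACCAGCGGTACAATGGCAATGGAGTGCGGCGCGGTACTCTCCGGCGTCAGTCTAGGGGCCTAAGGTGAACAGGATGCCTATCCACAACGTTATCGA
>AZIN1_syn
ATCGTCTTCTCGATTGCGCCGCTGTCGATGCACAAACCTAAGTGAAGCTATCCCTTTTAGCACTCCTCTAGGAAACTGGCAGGAACCGATAGATCATACTTCATTACGTTCGTCAGTCTA
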