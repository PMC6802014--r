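>gatB_a
CTTTTAGTATTCACACCCAGGTATATGATGCCCAAAATTTCTATGGTCGTACTAGATTGGTTGAGCTCTC
CACAGGTCCGAGCTAATGCTCTCGGTCCCTACGAGAAACTAACATCCTACGCACAAAAGGTTCATCAGAC
CACGTACGGTGTAATTGACTGCACCCCGGCGTAGATTCTAGCCCAACGCCGTGGCGTTCAGAGTTAGCGT
TACATAGATAGTGAAAAACTCCTAAGCGAGGTGCTCGCTAAGCTAAACCACACGCGATCCTTTAAACGAA
TCGTAGCCTCCACGATAGAACACAGGGGCGTTAACCCGTGTCCCTCCTCTCCCGGACGTCCCTGGTCGCG
ACTAAGTCGTCAGTTACCA
>gatB_b
CTTTTAGTACTCACACCCAGGTATATGATGCCCAAAATTTCTATGGTCGAACTAGATTGGTTGAGCTCTC
CACAGGTCCGAGCTAATGCTCTCGGTCCCTACGAGAAACTAACATCCTACGCACAAAAGGTTCATCAGAC
CACGTACGGTGTAATTGACTGCACCCCGGCGTAGATTCTAGCCCAACGCCGTGGCGTTCAGAGTTAGCGT
TACATAGATAGTGAAAAACTCCTAAGCGAGGTGCTCGCTCAGCTAAACCACACGCGATCCTTTAAACGAA
TCGTAGCCTCCACGATAGAACACAGGGGCGTTAACCCGTGTCCCTCCTCTCCCGGACGTCCCTGGTCGCG
ACTAAGTCGTCAGTTACCA
>gatB_c
CTTTTAGTACTCACACCCAGGTATATGATTCCCAAAATTTCTATGGTCGTACTAGATTGGTTGAGCTCTC
CACAGGTCCGAGCTAATGCTCTCGGTCCCGACGAGAAACTAACATCCTACGCACAAAAGGTTCATCAGAC
CACGTACGGTGTAATTGACTGCACCCCGGCGTAGATTCTAGCCCAACGCCGTGGCGTTCAGAGTTAGCGT
TACATAGATAGTGAAAAACTCCTAAGCGAGGTGCTCGCTAAGCTAAACCACACGCGATCCTTTAAACGAA
TCGTAGCCTCCACGATAGAACACAGGGGCGTTAACCCGTGTCCCTCCTCTCCCGGACGTCCCTGGTCGCG
ACTAAGTCGTCAGTTACCA
>gatB_d
CTTTTAGTACTCACACCCAGGTATATGATGCCCAAAATTTCTATGGTCGTACTAGATTGGTTGAGCTCTC
CACAGGTCCGAGCTAATGCTCTCGGTCCCTACGAGAAACTAACATCCTACGCACAAAAGGTTCATCAGAC
CACGTACGGTGTAATTGACTGCACCCCGGCGTAGATTCTAGCCCAACGCCGTGGCGTTCTGAGTTAGCGT
TACATAGATAGTGAAAAACTCCTAAGCGAGGTGCTCGCTAAGCTAAACCACACGCGATCCTTTAAACGAA
TCGTAGCCTCCACGATAGACCACAGGGGCGTTAACCCGTGTCCCTCCTCTCCCGGACGTCCCTGGTCGCG
ACTAAGTCGTCAGTTACCA
>gatB_r
CTTTTAGTACTCACACCCAGGTATATGATTCCCAAAATTTCTATGGTCGTACTAGATTGGTTGAGCTCTC
CACAGGTCCGAGCTAATGCTCTCGGTCCCGACGAGAAACTAACATCCTACGCACAAAAGGTTCATCAGAC
CACGTACGGTGTAATTGACTGCACCCCGGCGTAGATTCTAGCCCAACGCCGTGGCGTTCTGAGTTAGCGT
TACATAGATAGTGAAAAACTCCTAAGCGAGGTGCTCGCTAAGCTAAACCACACGCGATCCTTTAAACGAA
TCGTAGCCTCCACGATAGACCACAGGGGCGTTAACCCGTGTCCCTCCTCTCCCGGACGTCCCTGGTCGCG
ACTAAGTCGTCAGTTACCA
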