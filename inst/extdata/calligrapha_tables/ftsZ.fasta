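>ftsZ_32
GCAAAGACGACCCCTACTCACATGCTTTTAGAGGCGCACGGTTCTCAGCTCAGTTCGAGTGAGAGCGGCC
GGCTCAGAAGATGCTGCCTTTCCTAGAGATCGGAATAATACCATCTACCCATTTTGTATCGGGTTGTTTC
CAGCTTGCTTTCAGGAGTTGCCAACGCTAAACTTTCCGTCCTTTTACCGTAAATGCTACAAGAGATAGCT
CAATAGGCACGCAGGTACTCAAGTTACAAACGTTCCCGGATGTCTATCATGAACATATAGCGCTAGGTGG
TTTGAAGCTTCTTTCAAACTGCATGGAGCAAAGAAGAGGTAGGGAATCCCAGGTTGCTGTATTAGCAAGA
TGGTGCTCTGGTGAAAATATGCCTGCGACGAGTTTATCACCATGACGATGGATTTGCAGTGACGCAATAG
GCGTCTCCCGAGGGG
>ftsZ_b
GCAAAGACGACCCCTACTCACATGCTTTTAGAGGCGCACGGTTCTCAGCTCAGTTCGAGTGAGAGCGGCC
GGCTCAGAAGATGCTGCCTTTCCTAGAGATCGGAATAATACCATCTACCCATTTTGTATCGGGTTGTTTC
CAGCTTGCTTTCAGGAGTTGCCAACGCTAAACTTTCCGTCCTTTTACCGTAAATGCTACCAGAGATAGCT
CAATAGGCACGCAGGTACTCAAGTTACAAACGTTCCCGGATGTCTATCATGAACATATAGCGCTAGGTGG
TTTGAAGCTTCTTTCAAACTGCATGGAGCAAAGAAGAGGTAGGGAATCCCAGGTTGCTGTATTAGCAAGA
TGGTGCTCTGGTGAAAATATGCCTGCGACGAGTTTATCACCATGACGATGGATTTGCAGTGACGCAATAG
GCGTCTCCCGAGGGG
>ftsZ_75
GCAAAGACGACCCCTACTCACATGCTTTTAGAGGCGCACGGTTCTCAGCTCAGTTCGAGTGAGAGCGGCC
GGCTCAGAAGATGCTGCCTATCCTAGAGATCGGAATAATACCATCTACCCATTTTGTATCGGGTTGTTTC
CAGCTTGCTTTCAGGAGTTGCCAACGCTAAACTTTCCGTCCTTTTACCGTAAATGCTACAAGAGATAGCT
CAATAGGCACGCAGGTACTCAAGTTACAAACGTTCCCGGATGTCTATCATGAACATATAGCGCTAGGTGG
TTTGAAGCTTCTTTCAAACTGCATGGAGCAAAGAAGAGGTAGGGAATCCCAGGTTGCTGTATTAGCAAGG
TGGTGCTCTGGTGAAAATATGCCTGCGACGAGTTTATCACCATGACGATGGATTTGCAGTGACGCAATAG
GCGTCTCCCGAGGGG
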