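>coxA_33
GTATGTTCTTAATCCACGAACGTGGCACAAGAACGCTTCGACGATATGATTCGGGATTCACGGTTAATGG
AAGTCGGTTATCAACTTCCTGTTCCACTAATGTGAGGTATACGTTATATCAGCTGTAACGGTTGCTGTAT
AAAAGCAACGGTACAATGGTTTTAGGAGATCTTCTTTATTAGAGTTAAGTACGTACGTTATGCCGTGAGT
GAGGATGAGACCGATCACACAGGTACCCGACACGGTACTATATAAATCGGAAACCTATAGACGCAAGTTC
CCCTGTTCGCTTGTTCTACTGCGCCAAAAGGTGGAACAATGGCGAATTGGATCTCTAAGGTCATCGTTCT
CTACACTATAAAGAAAGACCGCAGACTCTGGCGTCATTACTATTGGTATGTC
>coxA_b
GTATGTTCTTAATCCACGAACGTGGCACAAGAACGCTTCTACGATATGATTCGGGATTCACGGTTAATGG
AAGTCGGTTATCAACTTCCTGTTCCACTAATGTGAGGTATACGTTATATCAGCTGTAACGGTTGCTGTAT
AAAAGCAACGGTACAATGGTTTTAGGAGATCTTCTTTATTAGAGTTAAGTACGTACGTTATGCCGTGAGA
GAGGATGAGACCGATCACACAGGTACCCGACACGGTACTATATAAATCGGAAACCTATAGACGCAAGTTC
CCCTGTTCGCTTGTTCTACTGCGCCAAAAGGTGGAACAATGGCGAATTGGATCTCTAAGGTCATCGTTCT
CTACACTATAAAGAAAGACCGCAGACTCTGGCGTCATTACTATTGGTATGTC
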