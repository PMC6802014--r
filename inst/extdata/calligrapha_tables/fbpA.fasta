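>fbpA_36
ACCTGTGGAGTTCCTCAGGGGTCGCATGTCCTCAGCGCACTGAGCCGGATGCGGCACCATTACTAAGTCG
GGCGATCCTAACCATAACTATAGAGGCTCGCCCATCATCTTGGCAGAAGTGCAATCTGAAAAGCGAAATG
GATGAGGCGTCTCTAGTGTTTGGCCGAGGCTATGGCCTAGACCCAGCGCTTCCCGTTTTACTCGGAAGTT
CTGAGGACGCACTAACACTACTTTGATTTTCATTTTGATTCCTACGCTCACATACGTATTGAAAGTCCAT
CTGATGCTTGCTATTGACGTCGGTTAGGAAGAGCCGCTTATGCGCTATAGCGGCCGCTCTTGGATTTTGA
ATCCGGGTTTTATCTGCGGTTAACTGATTAGTGACATTGCGACTGGCTCATCATAGAGTTCGCTAGGAAA
TGTTCGTCC
>fbpA_d
ACCTGTGGAGTTCCTCAGGGGTCGCATGTCCTCAGCGCACTGAGCCGGATGCGGCACCATTACTAAGTCG
GGCGATGCTAACCATAACTATAGAGGCTCGCCCATCATCTTGGCAGAAGTGCAATCTGAAAAGCGAAATG
GATGAGGCGTCTCTAGTGTTTGGCCGAGGCTATGGCCTAGACCCAGCGCTTCCCGTTTTACTCGGAAGTT
CTGAGGACGCACTAACACTACTTTGATTTTCATTTTGATTCCTACGCTCACATACGTATTGAAAGTCCAT
CTGATGCTTGCTATTGACGTCGGTTAGGAAGAGCCGCTTATGCGCTATAGCGGCCGCTCTTGGATTTTGA
ATCCGGGTTTTATCTGCGGTTAACTGATTAGTGACATTGCGACTGGCTCATCATAGAGTTCGCTAGGAAA
TGTTCGTCC
>fbpA_e
ACCTGTGGAGTTCCTCAGGGGTCGCATGTCCTCAGCGCACTGAGCCGGATGCGGCACCATTACTAAGTCG
GGCGATCCTAACCATAACTATAGAGGCTCGCCCATCATCTTGGCAGAAGTGCAATCTGAAAAGCGAAATG
GATGAGGCGACTCTAGTGTTTGGCCGAGGCTATGGCCTAGACCCAGCGCTTCCCGTTTTACTCGGAAGTT
CTGAGGACGCACTAACACTACTTTGATTTTCATTTTGATTCCTACGCTCGCATACGTATTGAAAGTCCAT
CTGATGCTTGCTATTGACGTCGGTTAGGAAGAGCCGCTTATGCGCTATAGCGGCCGCTCTTGGATTTTGA
ATCCGGGTTTTATCTGCGGTTAACTGATTAGTGACATTGCGACTGGCTCATCATAGAGTTCGCTAGGAAA
TGTTCGTCC
>fbpA_b
ACCTGTGGAGTTCCTCAGGGGTCGCATGTCCTGAGCGCACTGAGCCGGATGCGGCACCATTACTAAGTCG
GGCGATCCTAACCATAACTATAGAGGCTCGCCCATCATCTTGGCAGAAGTGCAATCTGAAAAGCGAAATG
GATGAGGCGTCTCTAGTGTTTGGCCGAGGCTATGGCCTAGACCCAGCGCTTCCCGTTTCACTCGGAAGTT
CTGAGGACGCACTAACACTACTTTGATTTTCATTTTGATTCCTACGCTCACATACGTATTGAAAGTCCAT
CTGATGCTTGCTATTGACGTCGGTTAGGAGGAGCCGCTTATGCGCTATAGCGGCCGCTCTTGGATTTTGA
ATCCGGGTTTTATCTGCGGTTAACTGATTAGTGACATTGCGACTGGCTCATCATAGAGTTCGCTAGGAAA
TGTTCGTCC
>fbpA_c
ACCTGTGGAGTTCCTCAGGGGTCGCATGTCCTCAGCGCACTGAGCCGGATGCGGCACCATTACTAAGTCG
GGCGATCCTAACCATAACTATAGAGGCTCGCCCATCATCTTGGCAGAAGAGCAATCTGAAAAGCGAAATG
GATGAGGCGTCTCTAGTGTTTGGCCGAGGCTATGGCCTAGACCCAGCGCTTCCCGTTTTACTCGGAAGTT
CTGAGGACGCACTAACACTACTTTGATTTTCATTTTGATTCCTACGCTCACATACGTATTGAAAGTCCAC
CTGATGCTTGCTATTGACGTCGGTTAGGAAGAGCCGCTTATGCGCTATAGCGGCCGCTCTTGGATTTTGA
ATCCGGGTTTTATCTGCGGTTAACTGATTAGTGACATTGCGACTGGCTCTTCATAGAGTTCGCTAGGAAA
TGTTCGTCC
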