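>hcpA_42
GGCATGTAGAGTTTCCGGCAGAGGAAGCGATGATAGCATGCTAAAGGCAGATATGAGTTTTCAGGTTACC
GGCGGGGATATTTGAGATTGATGTGAGTCGTGCTTAATTTTAAACCTATTGTTAGAACTGGCAAACGAGC
TAGGGGCACATTATACCGTGCTGCTACTACCCGGGAGCTAGCAGGCATAATCCAGCCGCGTGCACAACTA
AGCTAAATATCTAGGCCGACACGGCGATGTGTGCTAGGATTCTAAGACGAGGCTGCTACGGTTGCTAATC
CATATCGAGAGGTCATGCTCATAATGACAATTGCCACGTAGCAAGGAACTGAAGTTAGGAACTACCCGGG
CTCATAGGCATCATCATCATCGACCAGCTGCCCACTGTCGATCTACTCGAGGGCCGTATACTCCCTAGGG
TTATTGTGGTATCCAGGTCAAGGA
>hcpA_c
GGCATGTAGAGTTTCCGGCAGAGGAAGCGATGATAGCATGCTAAAGGCAGATATGAGTTTTCAGGTTACC
GGCGGGGATATTTGAGATTGATGTGAGTCGTGCTTAATTTTAAACCTATGGTTAGAACTGGCAAACGAGC
TAGGGGCACATTATACCGTGCTGCTACTACCCGGGAGCTAGCAGGCATAATCCAGCCGCGTGCACAACTA
AGCTAAATATCTAGGCCGACACGGCGATGTGTGCTAGGATTCTAAGACGAGGCTGCTACGGTTGCTAATC
CATATCGAGAGGTCATGCTCATAATGACAATTGCCACGTAGCAAGGAACTGAAGTTAGGAACTACCCGGG
CTCATAGGCATCATCATCATCGACCAGCTGCCCACTGTCGATCTACTCGAGGGCCGTATACTCCCTAGGG
TTATTGTGGTATCCAGGTCAAGGA
>hcpA_b
GGCATGTAGAGTTTCCGGCAGAGGAAGCGATGATAGCATGCTAAAGGCAGATATGAGTTGTCAGGTTACC
GGCGGGGATATTTGAGATTGATGTGAGTCGTGCTTAATTTTAAACCTATTGTTAGAACTGGCAAACGAGC
TAGGGGCACATTATACCGTGCTGCTACTACCCGGGAGCTAGCAGGCATAATCCAGCCGCGTGCACAACTA
AGCTAAATATCTAGGCCGACACGGCGATGTGTGCTAGGATTCTAAGACGAGGCTGCTACGGTTGCTAATC
CATATCGAGAGGTCATGCTCATAATGACAATTGCCACGTAGCAAGGAACAGAAGTTAGGAACTACCCGGG
CTCATAGGCATCATCATCATCGACCAGCTGCCCACTGTCGATCTACTCGAGGGCCGTATACTCCCTAGGG
TTATTGTGGTATCCAGGTCAAGGA
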