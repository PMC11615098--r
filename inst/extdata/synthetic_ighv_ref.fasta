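>IGHV1-2*01|IMGT
ATGCCCGAGAGTTCCTGATAGCTTTTGTTCCCCACGGAACGCTATCGTCATTTGCATCATCTCCACTGCCCCGATGTCTG
CTATGGACGGCTTCACCTGATGTGGAGCGAGGGTACTGATAGATATACGACAATGTAATAAGACAAAACTCTATGTGTAA
CACGGGAAGTAGAAGCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTTCACGCCGTAAAGTACGATTAGGATATTC
ATCCCTTCCCTGTATATGCCGAATGTTCTAATAAACAACTTGGCGACAAGTCGCCTAGAAAGGTGCCGCTGGCATAACAA
GCCTCCTGCTTGCCGTCTTCAACGTCATGACCCGCGTACATCACAATGCCTCAAGCCGGAGTCTAGGCTTTGAAACAGCT
GAATAAATCGTGTGCATACGTGAGTCGCCGGAAAGTAGTTCACAGTGTGCACGTAGTCTCGATACGTCATACAAAAACC
>IGHV1-2*02|IMGT
ATGCCCGAGAGTTCCTGATAGCTTTTGTTCCCCACGGAACGCTATCGTCATTTGCATCATCTCCACTGCCCCGATGTCTG
CTATGGACGGCTTCACCTGATGTGGAGCGAGGGTACTGATAGATATACGACAATGTAATAAGACAAAACTCTATGTGTAA
CACGGGAAGTAGAAGCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTTCACGCCGTAAAGTACGATTAGGATATTC
ATCCCTTCCCTGTATATGCCGAATGTTCTAATAAACAACTTGGCGACAAGTCGCCCAGAAAGGTGCCGTTGGCATAACAA
GCCTCCTGCTTGCCGTCTTCAACGTCATGACCCGCGTACATCACAATGCCTCAAGCCGGAGTCTAGGCTTTGAAACAGCT
GAATAAATCGTGTGCATACGTGAGTCGCCGGCAAGTAGTTCACAGTGTGCACGTAGTCTCGATACGTCATACAAAAACC
>IGHV6-1*01|IMGT
ATGGAGTGCGTAGGCGCCAACCCGCATTTAAGGAGTCCGCATCGTATTTCCCCGCTACGATGCTTTGCACAAATTCTACC
GCATTGATCGTGGATTACTAGTTTTGATGGCATGGGTAATGGTGGAGCCAAACATCCAGCCTCGAGTACGTGAAAATCTA
ACGACCCCGGCGCAAGGACAGACTAGTCGCCGTTGAGAGGACTCCAGTACAGGCGAGGTATCAACGACGATACGACTCGG
CTGGCAAACACGCGGTTTATCTATGCAGCTAATATCCTTAGTAGTCGTCCCCTGAGACGATCTGCCATCAGGCGGCGTCC
GACGCTCCAACGGCTCCTACAGACTCGTTCTACCGGACCAAGGGACTCGAACATCAGATGGACAGACCTCGTCATAGCCG
GGCCATGTAACACTGATATCTCCGGGTAGCTCATCACGAGCACCCGACACAGTGTAGCAGCTGCAAGCTTTGCCTACACA
AAAACC
>IGHV6-1*02|IMGT
ATGGAGTGCGTAGGCGCCAACCCGCATTTAAGGAGTCCGCATCGTATTTCCCCGCTACGATGCTTTGCACAAATTCTACC
GCATTGATCGTGGATTACTAGTTTTGATGGCATGGGTAATGGTGGAGCCAAACATCCAGCCTCGAGTACGTGAAAATCTA
ATGACCCCGGCGCAAGGACAGACTAGTCGCCGTTGAGAGGACTCCAGTACAGGCGAGGTATCAACGACGATACGACTCGG
CTGGCAAACACGCGGTTTATCTATGCAGCTAATATCCTTAGTAGTCGTCCCCTGAGACGATCTGCCATCCGGCGGCGTCC
GAAGCTCCAACGGCTCCTACAGACTCGTTCTACCGGACCAAGGGACTCGAACATCAGATGGACAGACCTCGTCATAGCCG
GGCCATGTAACACTGATATCTCCGGGTAGCTCATCACGAGCACCCGACACAGTGTAGCAGCTGCAAGCTTTGCCTACACA
AAAACC
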