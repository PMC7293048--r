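>pENTR-AtTAS1c-D2-Bc-synthetic
TTGGTGTTACTTCTGGTTCCCTATAGCCCTCGCAGGGCTAGTTAACAGGAAGGAACAGTTGCATCAGTACCTTACCGTCA
TGTAGAAGATGCTGTATATAATTTTGCCCTACGCGTCGCGTCCGCGTACCATAGATATTGATAGGGCAACTCAACATTGA
AACGGCTGGCGGCTGCATTTAGGAGACCTACAGATGATTGTGTGGCAACAGCTTCTGTTACTATGATTAACCAGCAAGTT
AGGATATTGTACTACGTTGATGAAGTGGCGACCAGCTCGTCAGGATGCATTATGGCAGTCTCACTGTGTAATGAATACGA
ATCCATGAAGAGACAAAAATGTTCTGGGTATAGGTAATTATTTGAGCCACCCGGCCTAGCAAGCCATGACCTCTAGAGGC
TGAAGCCCGCCTCCGGCTAACCCTCGGATCGCCGGGAGGTTAGATAAACAGTATGCATCGAAACGAACTTCAGCACAACT
TGCTAGATGGTGCAGGAGTTGTTTCCGTGAATGACGGTGGGGGTTCCCGATCAGCTGCTGTTCCCCTGCAGTGACACGTT
GAATGAGAGAACGACAATCCGCTTATGGTCTTACCAGCATTGACCATATGGATGTCAAATTAAGTTGGCTAAGTCCTAGA
CGTTTGAGAGCGGCGAGCGAATACTCTATCCCGGCAACCGTCAAACTCACCGCACTCATAATCAGCCGTTCCGTTCTTCA
GCCGTCTTCCCATTAGTTCCTCGGACCCTCGCGATCCGCCTCTCCCTCACTTGCTGAATGCTAACTCTGGAGGCCTGTAG
TTTGCGACCATGATTCACGGTACCCATGACGGAGCGAGAAACAGACAGATAACATAATATTTCCCCGAGATATCAATGTG
CGGACAAATCACGATGGATTCGATAAGCTGGCGCTGGACCTGGGCACGTGCACCAAGTCGAGTTAGGAGGTCCCTTTGTG
ACGACACCACTAAGACAGACAAACTAATTCCTTCCTTAAAACAGGCTTTCTTGGTCGAGAGCTACGCTGATCTCATTCAA
TCTTTGTCAGTACTTATCTCTAAGTACGAACAAGCGGACTCGCTGTCCAACATATCTTGGCGTCTTACCCTGCGCCTCCT
GTGAGCCAATTGTATGAGTCCGTATCCTTGAAACGATTCCCAACCGCCTACCTGGCTCGGTTGTAATATTGTGACGCGGA
GCTTATTCAGGCTCGGTCAACATCAAAGGATCGGCATCTCTAGGACGGGCACGCCAGATTTTATGTAGAGAATTTCTCTG
CCAACTAGAATCGATGCTACCCCTGTCCCGGTCCTTTCAATTGGTGCCGTACAGCCGCGAGTAATGTAGCATTGCACATA
ATGCTTAATGCAAGCTGCAGCCCTACGACATAAGGAGATGTCACGTACCTGAAAACGTAAGGGCAGTAAATTTTCAATAC
CTGCTGAGCCCAGGCGTACTTTAGTGCGCGGCCGTAAACGCGAATGGGCCTCGGATTCTCCCACAACCCCCACACGCGTC
TAGACATTGCTTGATAATGTCGGCCGTCGCTCCCTCGAAAGGTTCGATGTACATGTTGACTAACCGTGTTTAGAGATGCA
ACAAAGTTGACTCCCGATGCGAGGCGGTGTCGGTCTCATCGGCTCTCGGTTGAGACGGACGAACAACAACCCTGTTGATA
AGGGAAGATTTTAGCTAAATGATCTAGGCGACGGCCCTCTTTATGCTACTACACCTTGCTAAGACTGAACGCCCATAGTG
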