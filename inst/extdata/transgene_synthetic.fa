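>synthetic_CMV_Luc synthetic stand-in cassette; promoter [0,600), reporter [600,2253); embeds published primer sites
GCAGGCCCCGCTGGGCACCGAAAACGACCAGTGGAAACTCGGGACAGGGACTGCAACTTAGGGCCTGTGT
TCCACTGGCTCGTTTTCGCAGTCCAATTATGAGAGAACCCGTCAGAAATTCGGCGGTCTAGCGCTCAAAA
TAAGCGGTCGGAGACCACGCACCTCGATCAGTATTACAACATAATCCGTTAGCTCATTAAAACCTAGGGC
GTGGATAGCGGTTTGACTGTTCCGATAGGCTCTATTCTGACTGGTGTGAACAGCAGCTCCGACAGTAGGA
TGTGAAGGGTCTATTCGACAAGCTCACTTACGGTAACAACTCCGCCCCATTGATATTTTGCGTGGCGGAG
AAACCAACCTCAGTGTTGGCTGAGACCACCGCATACAGGCAATATAGTTGATTATGCTTACCAATAAGCC
ATCTGAGCGACGCGCTTGCGACCCGCACCAGGCGCACTTCAGCGAATTGGTGCGGCCATTATTCTGTCCT
TTTCCATGACGAGCGGCTCCGCCCTTACCTAGCCATAATCCATCCCTAAACCCTGAAAGACATCGGAGAG
AAAGTATGTATGGGTTTGTCTACTGGCACAATTATACAAGTCGATTTATATGAAGAGATACGCCCTGGTT
CATGCCGGTATAACGGATATTTTGCTTGGGCTCCTGTGTCTAGGCCACACTTGCTCCCACGAGAGGTTAT
CAGTTGCGACGTTCTTGCGAAGAGAAATACGTAGGAGGCTACAAACCTCTGTTCATATAGCCAGTAATAG
GACATAATGAGACTGGCGATTCTTTATGCCGGTGTTGGACCGCTGGTGAAATGACACCCACCGACAAATA
TAGACTCTTATAACGAACACTCTCAGATCTCTGTCAAACAGTGCGCGTTAAAAAAGGGGATTGACGGGCC
TTGTACGCTACCTCCGCCGAGAGACCTACAGAGTAGAGCCCAAAGGTCTCCCGGAGAGGGTCCCCCGGCC
GACTTCAGGGCACGGGCGCAGTTGTTAATTCGCTTTCACGCGGTCATATACCGGTAAGGGCAGTCCGCCT
GTATGCCTCAAGGTAAAGATAGAGTTAGAGGGTCTGGGCTTAAAGTGGCTATTTTCGATCGGCTAGCCAA
GAGCGATAAATACTCGCCAGGAGGCAACGTAATAGTAACATAGCGGGGTACGCGTACGGGAATTCGTTAT
CGGACGCGAACGATCGCCACGCAACTTGCAGTGGATGTCTGCCCTATGGCGTCCAGGATATTATGGTATT
GAAAACGGTAGATTCTCATCAGCAAACATTATCTGGATGAGAGTCACATATGGTAAAATTCGATCTACAG
GGCCAGTCGCGGCGGCCGTATGAACCCGTATTGATGTGGTAAAGCTCGTATCCTACCCCGCCTACGGGAG
GTGTTGGGCGCGTTATTTATTGATATTAATTCAGCTATGATACGGCGTCCAACGACTTCACCTGAGCTCG
TAGTCGGCTTGGACATTTCGCAGCCTACCGTAAATGCTATGACGGGTTTCGAAGGTCATTAGTAGGCATG
ACCGGCTTTGCCTTGTACCAGGATATATTATAAACGTAAAAAGGGAGGCTGGGGTGCGACACTCTTTGGA
ATGAGCTCTACCTCGCTCTGGTAGCCGATTAAACCTTTAGAACCGTTAAAAGCTAGGATAGAATTTCTGT
GGTGGGTGCATAGATGACCTAGGGCAACTTTGGAGGATTCAGGTGATCAAACCAAAGGCCAATAGAGCTT
TTTTTGAGAAGTCTAAGTAAACATTTTGGTAGCCAAAGCACTATCGACTGCGGGTGTCTGGCTTGCCGGT
TAGTACTCACGAGTCCGCGCAATACGGGAATAGCGATAGGATGCATTATAACGTGGTTAGAGAATGCGCC
TGAGAGAATCCACCGCGATTGAGCAGACGTTCTGCTTCGACCGGAAAAGCGGCTCTACGAAGCTTGGCGA
ATATTGAAAGACCTCCGGCTACCCGGCGTGAGAATAATCCCACCCTGTTCTCGTGCCGACACCTAGCCTG
AATGGAGCTGAGTCGTCTAAACAGAGCGACAAGGTTAAGGTGATGTACGGTCGGTGAGCACACTCCACCC
TATTGCACTCTACTTCTCTACACGCGCGCCCATGCTAGGGCCCGACGCTACTCACGTGTACTACCGCGCT
CCAATCTTCGATGGATGAATCTACCCTTTGCGTGTTGGGAGTCGGGACGAAGTCGGGCCTTAGCGATGTT
ATGGATCGAAGCT
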