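>SSU_16S
AGAAGTCTAGAGTTTGATCATGGCTCAGGGATATCAGTTCGCTTTTTGAGTGCTAACTATCGGTATAGGG
GCGATCTTAAAGTGTCTTATATTGACCTTGAGTAAAGCCGTCATAGTTTGGTTGTGTCGTCGAACCATAG
CTTAATTATTTGTGCGTCAACACCAATTCCAGATGGTGCAAGTATATCACCCGGATAACCCGCTTGTTTC
GGGCCCAGGTGTATACGCGCAGTGTAGTCCAAGATATGATAGCGGGTCCAACAAAGGCCGACATGAGTGT
AACGGGCTATTATTGTTAAAAGGCTCAGATCGCCCGCCAAGCCACCTGTTACTCTGAATCAACGGAGTAA
TGAGACTTTGATCGACGGTCGACCCTTGTTATACAGTCTCACTATTTCAGCTAAAGGTCTGATACGTTGC
CCTAAGAACGTGCCGGTCCCGACGTATTTCAGCCGCCGTGTTATGTTCACAGCCGTTGGTAATAAGCTTA
CTCTCCCCGTTTATGCCAACAACACGTGCCAGCAGCCGCGGTAATTTACCTAATAACCATTTGCTGCAGT
CATTCCCCAGCCGCCGGTGTAAAATTGCTCAGTGCGCTTTCGTAGCCTCAGTAACCGGCGAGATCGCGCT
GGGCCTACCGCTCCAACAGGACTGAGCTAAAACGGCCTGGGACTTTCGCATCCATACACCTCGTAAGCGC
AAATGCGCGGTCAGTACTTTTAGTTAAGGTGGTGCGCAACGACATGCTGCGTCTGGTACAATCGAAAACA
TTGCGGATAAGAACAGTATTAGATACCCCTGTAGTCCCACTTCATCTAAGCCGCTTTGAGGTGTGCACCG
TTATCTCCGTATAAGAACTAGGGGATTTAGACAAGACTCACGTAGGAGGATGAACCGGTTACAGCTCGTT
GTGAATCCGGCCAGGTGTTCGGACCGGGCAACGCTCTGATAATTTTCAGAATTTGACCTGCCCGTTGAAT
GGAGAAGCTGCGATACTGCCGCTTCTACCTTTGTTAAATTTTCTGGTTACAACAGAGATGCGGCGGGCAC
CTGCAAACGGTGCTCGTTGGCAGACTCAAGAATATTCTAACACGGCGCGGTGTAAGCGACTATGCGGCTC
AAACGAGAGCCTCACTCAGTCATTACGCAGAGTGAAACAATGATGACCTAAACCAAGTATGCTCGGTCCG
CACCAAGTCTATCACCGGGGTATTAATGCCGCCTACTGCAGGCCGTATCCAACCCGACAGCCCCCCCCCC
AGGTTCTTCTGACTCGCTTCGGACGCGGGGCGTCAGATAGCTCAGAGTTCTGGAAGGTTTACCGGGTGAG
GCGTCAGGGCAGACATTTACAGTGGCGTAACCGGTCTGCATGGTTCGCTGCCTTCCTACCATCGGGGAAC
CCCGGCGAAGTCACTTTCTTCGATAATGGCTCAGGAACCGAAATAACCCATAGCCCAATGGAATATTTTA
GTGGCACGGGTACATTACCCTCCGAAACTAGTATGCCTTTAAGTCGTAACAAGGTAACCCCACTATACCT
CT
>ITS
AATGGTACTCATTCTCCCGGATTGAACACCCAGCTGCCAAAAACCGGGGGTGCGAGATCCCTTAGACACC
CATGCTCTGCAGTATTCCGGTTCTGTATTCAGTGTGATGTTATCGTCACGGGAATCCCTGCTCCGTCGAC
TGTCGTCAGGCTCACACGGAAAAAACACGTAACGCAACGAGTGAGGCCTCTCACTGGATCCAATCGCGCG
CGCCACGTGCAAGACATGGATTTAGAGGCCGTAGGGCCGGCGCCGAACAGGGGTACCGTATACCAGAGGC
TAGATGGTTGAGTTCGAGCACTTAATCTTTCAATCATGTTCGAGTAATGCGGTGACTGGAATCGCCGCGC
TTGACCGTCGGTCCAAGCCTGAGTTCTAACCACGGGACTCTCTCCTGTGC
>LSU_23S_PREFIX
ACCACAGTTGTGAACAGATAGCGCTCTATTAAACTTTAGCCGGCGTTGGGAAGGGATTTAATTGCTCGAG
AGGCGGGTCGAATACAACGCCTTCGGAGAGGTTAGTCAGGGATGTTACTGAGCCCTGTGCTCGAAGTTCT
TCACATTCTGAGCGCATTTCATCGCCCTGGTGACGTACGTTACTGTCCCCCCAATATCGATCGTCTGTTC
ACTACTGGCGTATCACGCAGGTCCGAAGTTATCAAAATCATCTGAGAGGTAGAACGTCGTCTATGTAATA
AAGAGCTATTCCAACAGGCTAGTTCTCAGGACAAACTGGCTAGTCCGCGAGGCCGTGACACTTGTCCGCA
GCGTGGTAGAAGAGGGCCACAGTGTCGACACGATCAAACTTTATCCGGTGCAATCTTAAGCAGGAATCAG
CACTTCCCATTTTGTTCGTACGCCGCAGTCCAATTCTCTGGGTTGTCTGGTATGGAATTTTGGACCATCA
GGTAGTAAGAAGTTTGGCAACTACTCAAGCCGCTAACTGTACAGCAAAGTTACGCAAGAGCACTCTAAGG
CCCGTGTTGTACATGAAGCCCATCTTCTCTTTTTCTGTTTATGGTCTTCCTAATTTACGCATCGATAGAC
ACGATCGAGATCTGAGCCCCGCTGTGAGTTATTTCCCAAAAGAGTCAATCCGAGTGACAGAATAGACATA
ACGGACTACGATTCTAATTGTGGTAGCGAATGGAAAAGGTCATGGAGGCTCTTGTGCAACTCTATATCAT
AGGTCTCGCCATAGAAGCCCGATTATTCTCTCCGTGCGATACAACCGACTCCGCTACATGTGCCTAGCTA
GCAGGTGTCCATTTCGTGGCAAGGCTGACTGATTGCTTTGTCAAATCTATCATACAAAGT
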