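>SIMG001_EST01
GTATCGAAGGCAAAGATGTACTTCATATTCGCGCGTACATACCTGGATGTGATGGGATAGCCAGCGAAGCTCGCCAGCCG
GACCACGAACATACAGTATTCTGACACCACAGAACAATGTTCAAGGAGCTTATGTATATCTTGTGAAACAATCTGTAACA
CTCACGGATAATCGGTATAGATCAAGAAAAGTCTTAGCGGGACCCGTCATATGTCCGGACTCTAGGCTCAGCTGGGAGCG
CGTAAGTGTCGCGATGTGGCTAGGTTTCTAATAGCGCAAGCGGACGTGCCGCACTCTGACAACCACGTTGTTTGTTTGGA
TCCATTGAAATCGTGAAGTTCCTCTGAATGGGTCACGTCGGCGATTTGTGGGC
>SIMG001_EST02
TTTTGCTTGGATCTTGTAATTGACAAACAAGAACTAGATGACCAGTATCGAAGGCAAAGCTGTACTTCATATTCGCGCGT
ACATACCTGGATGTGATGGGATTGCCAGCGAAGCTCGCCAGCCGGACCATGAACATACAGTATTCTGACACCACAGAACA
ATGTTCAAGGAGCTTATGTATATCTTGTGAAACAATCTGTAACACTCACGGATAATCGGTATAGATCAAGAAAAGTCTTA
GCGGGACCCGTCATATGTCCGGACTCTAGGCTCAGCTGGGAGCGCGTTAGTGTCGTGATGTGGCTAGGTTTCTAATAGCG
CAAGCGGACGTGCCGCACTCTGACAACCACGTTGATTGTTTGGATCCATTGAAATCGTGAAGTTCCTCTGAATGGGTCAC
GTCGGCGATTTGTGGGCTCTATGCCTCCTTCGAATTTCTAACTGCAACCGTATACTCAAGTGCCT
>SIMG001_EST03
CCAGAACTAGATGACCAGTATCGAAGGCAAAGATGTACTTCATATTCGCGCGTACATACCTGGATGTGATGGGATTGCCA
GCGAAGCTCGCCAGCCGGACCACGAACATACAGTATTCTGACACCACAGAACAATGTTCAAGGAGCTTATGTATATCTTG
TGAAACAATCTGTAACACTCACGGATAATCGGTATAGATGAAGAAAAGTCTTAGCGGGACCCGTCATATGTCCGGACTCT
AGGCTCAGCTGGGAGCGCGTTAGTGTCGTGATGTGGCTAGGTTTCTAATAGCGCAAGCGGACGTGCCGCACTCTGACAAC
CACGTAGATTGTTTGGATCCATTGAAATCGTGAAGT
>SIMG001_EST04
TGACAACCACGTTGTTTGTTTGGATCCATTGAAATCGTGAAGTTCCTCTGAATGGGTCACGTCGGTGATTTGTGGGCTCT
ATGCCTCCTTCGAATTTCCAACTGCAACCATATACTCAAGTGCATGGTATAATGGATCCAGCAGACCATTGAGTGGCGAC
CGGCAATCACATTTTGTTTGCAGTTACGCCTGAGCGAAGGGTATCTCACACAAGAATGTCGGGAGGTGCAGCGCAGAGCG
CGAAGTTAGAGTATCGTCGGACGCGTCAGCTTAACAGCTGAGCACCCAAGAACTTAAAGTAGGACGAGGTGAACACTAAT
GACCCAGACGTCTAT
>SIMG002_EST01
CGCAAGTTGCGTGGTCGCGACTGCGCTGCGGATCGCGCACTGCCAAGAGGGGAATGCAACATGGCACCCTGTATTGCCTT
AGATACGCTAAAGTGGCGGACACTTACGTGGATACTCACCGACGGCATTTATTACGAGCCTGTTCTTGGTAGCAAGTTGT
TCTCCGCAAACGCAGTTGTATTTATTGCCTGCTTGGCGCTACAGCCCAGCGCCATTCAGTTGGATCAAGTATTAAGCGCG
CAACCCACGGGTGCCCAGTCATTATCCGGCGGCCAAGCAGCTGCTGTTCGGGTGAAGGAAGATATATAAGTGAACAGTTA
TCACCATCCGTGAGTGACTAACTTACGTAGTGGGAATTTCTAATTTTTCGGAATCGGCTACACAGAGGTATCGACCGCAG
GAAAGTCGTTGGCTAGATTTACATTTCAATAAAACGCCTCGCTTCAACCGTCATCTGGATTACACAAGCGATTGCCAACC
GGCGTCGTATCCGTGAATGACGGAGTAGGAGAGGGTCCGCT
>SIMG002_EST02
ATTGCCTGCGTGGCGCTACAGCCCAGCGCCATTCAGTTGGATCAAGTATTAAGCGCGCAACCCACGGGTGACCAGTCATT
ATCCGGCGGCCAAGCAGCTGCTGTTCGGGTGAAGGAAGATATATAAGTGAACAGTTATCACCATCCGTGGGTGACTAACT
TACGTAGTGGGAATTTCTAATTTTTCGGAATCGGCTACACAGAGGTATCGACCGCAGGAAAGTCGTTGGCTAGATTTACA
TTTCAATAAAACGCCTCGCTTCAAACGTCATCTGGATTACACAAGCGATTGCCAACCGGCGTCGTATCCGTGAATGACGG
AGTAGGAGAGGGTCCGCTCCCAGAAATGCTAATGGCC
>SIMG002_EST03
GTCTCGACCCCGTTGTATATCGGAATTTATGGATTCATTCGTCATTGCTAAACACGCGTTCTTAGCTGCAAGGTTAGGCG
TCTCTGTGGACTGGGGGCTTGTCAGACGGACCTGGTTATCTGACCTATGACATCCCCACACGCCGCCCCCCTCAGTCCTC
CCCAGGCGTTTGATAACCCGGCTCCTCGCAAGTTGCGTGGTCGCGACTGCGCTGCGGATCGCGCACTGCCAAGAAGGGAA
TGCAACATGGCACCCTGTATTGCCTTAGATACGCTAAAGTGGCGGACACTTACGTGGATACTCACCGACGGCATTTATTA
CGAGCCTGTTCTTGGTAGCAAGTTGTTCTCCGCAAACGCAGTTGTATTTATTGCCTGCTTGGCGCTACAGCCCAGCGCCA
TTCAGTTGGATCAAGTATTAAGCGCGCAACCCACGGGTGCCCAGTCATTATCCGGCGGCCAAGCAGCTGCTGTTCGGGTG
AAGGAAGATATATAAGTGAACAGTTATCACCATCCGTGGGTGACTAACTTACGTAGTGGGAATTTCTAATTTTTCGGAAT
CGGC
>SIMG002_EST04
GCTAAACACGCGTTCTTAGCTGCAAGGTTAGGCGTCTCTGTGGACTGGGGGCTTGTCAGACGGACCTGGTTATCTGACCT
CTGACATCCCCACACGCCGCCCCCCTCAGTCCTCCCCAGGCGTTTGATAACCCGGCTCCTCGCAAGTTGCGTGGTCGCGA
CTGCGCTGCGGATCGCGCACTGCCAAGAAGGGAATGCAACTTGGCACCCTGTATTGCCTTAGATACGCTAAAGTGGCGGA
CACTTACGTGGATACTCACAGACGGCATTTATTACGAGCCTGTTCTTGGTAGCAAGTTGTTCTCCGCAAACGTAGTTGTA
TTTATTGCCTGCTTGGCGCTACAGCCCAGCGCCATTCAGTTGGATCAAGTATTAA
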