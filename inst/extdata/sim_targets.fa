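>SIMG001
ATGAATACCGAGTACTCCCTCCTAAGGACATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTAGATGACCAGTAT
CGAAGGCAAAGATGTACTTCATATTCGCGCGTACATACCTGGATGTGATGGGATTGCCAGCGAAGCTCGCCAGCCGGACC
ACGAACATACAGTATTCTGACACCACAGAACAATGTTCAAGGAGCTTATGTATATCTTGTGAAACAATCTGTAACACTCA
CGGATAATCGGTATAGATCAAGAAAAGTCTTAGCGGGACCCGTCATATGTCCGGACTCTAGGCTCAGCTGGGAGCGCGTT
AGTGTCGTGATGTGGCTAGGTTTCTAATAGCGCAAGCGGACGTGCCGCACTCTGACAACCACGTTGATTGTTTGGATCCA
TTGAAATCGTGAAGTTCCTCTGAATGGGTCACGTCGGCGATTTGTGGGCTCTATGCCTCCTTCGAATTTCTAACTGCAAC
CGTATACTCAAGTGCCTGGTATAATGGATCCAGCAGACCATTGAGTGGCGACCGGCAATCACATTTTGTTTGCAGTTACG
CCTGAGCGAAGGGTATCTCGCACAAGAATGTCGGGAGGTGCAGCACAGAGCGCGAAGTTACAGTATCGTCGGACGCGTCA
GCTTAACAGCTGCGCACCCAAGAACTTAAAGTAGGACGAGGTGAACACTAATGACCCAGACGTCTATTTCATTGTT
>SIMG002
TGCTCGTCGGGGACTCACGTCAGAGCACGTGTCTCGACCCCGCTGTATATCGGAATTTATGGATTCATTCGTCATTGCTA
AACACGCGTTCTTAGCTGCAAGGTTAGGCGTCTCTGTGGACTGGGGGCTTGTCAGACGGACCTGGTTATCTGACCTCTGA
CATCCCCACACGCCGCCCCCCTCAGTCCTCCCCAGGCGTTTGATAACCCGGCTCCTCGCAAGTTGCGTGGTCGCGACTGC
GCTGCGGATCGCGCACTGCCAAGAAGGGAATGCAACATGGCACCCTGTATTGCCTTAGATACGCTAAAGTGGCGGACACT
TACGTGGATACTCACCGACGGCATTTATTACGAGCCTGTTCTTGGTAGCAAGTTGTTCTCCGCAAACGCAGTTGTATTTA
TTGCCTGCTTGGCGCTACAGCCCAGCGCCATTCAGTTGGATCAAGTATTAAGCGCGCAACCCACGGGTGCCCAGTCATTA
TCCGGCGGCCAAGCAGCTGCTGTTCGGGTGAAGGAAGATATATAAGTGAACAGTTATCACCATCCGTGGGTGACTAACTT
ACGTAGTGGGAATTTCTAATTTTTCGGAATCGGCTACACAGAGGTATCGACCGCAGGAAAGTCGTTGGCTAGATTTACAT
TTCAATAAAACGCCTCGCTTCAACCGTCATCTGGATTACACAAGCGATTGCCAACCGGCGTCGTATCCGTGAATGACGGA
GTAGGAGAGGGTCCGCTCCCAGAAATGCTAATGGCCCGGCCC
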