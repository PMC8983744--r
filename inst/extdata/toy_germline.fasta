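>IGHV1-2*01
CCCTCGAGTCTGAACTTCGCGCCTCGTCCCCTTACCACCTTCTCAGCGCGGCCCGCTGGTCTATGGAAACCTGCCTCAGTGTCTTCCGACAATTACTCTTTCGTCGTCCCTGTCATCCTACGATGTGGAGATACTTGGTGTGTCCCTCCCTTGTCATGGGCAGGCCTGGCTATAGCCAGTTTACTTAGACCCGAGTCGGCAAGGGATTTTGCCAGTGACCTAAGAGCTAATGAAGCCCACCAGGTGACCTCATCCCTGAGGTTTGTTCAATTGTTGAGGCCTGACAATGATTGTGCGAGA
>IGHV3-11*01
GCGTCTAACTGCAGTTGGTTGCACCTGGTAGGTGTCGCCTATGCTAGTAGGGTGACTCGGAAGGACCGTCGCTGCTCACGGCATGGACTCACATGCCAGGATCCCAGACAGGGTGTAGTGCATATGCCCAGAACCTACGAACAAGCACGAGACTGTACTGAGGACCCCTCTCTCCAACCTAGTCAAGCTCTAAGTATAGGGGCTATTACCATAGACGATGTCCTACGCTGCTCGTCTAGGTTTACAGAGAAGCCGGATTACAAAACATTCATCCGAGGCGACCCCGGCTATTGTGCGAGA
>IGHV3-23*01
ACGAAAAACGGGTCCGATCAAGGCTCCCACACTTGCAAGGGGATAACCTCATATCAGCATAGCTGTGTCATCTGTGGTCGTCGACGCGTTGGGGATATATATGCCCGCACACCCATCAGATATCGCAATGGTACCCTAGGACTAGCATATGTAACGACTGGTAGGCATATTGCACTCAGGGTTGGGCATGCTGTGTCACCGTCCGATAATGTTCTGACCGTGTTAAGTAAGCAAATTCATACCCATCTGCGCCGAACCCGTTGGCCATACTATAATTGGCCAAATCTAGGATGTGCGAGA
>IGHV4-34*01
TCTGATGCCTGGCCGTCACGATGGGTGATTGGTGCTCTAGTAGAGAGAGGGTCACTGCTTAGACCCCAGAATTTGGGCAGTGCGACCTCCGTGCACACTTTAAATTCACCGGAAGCTGCGATGTTCAGCCGAGTGAGCAGTCCTGTTACTTTAGAGAGTCTGGTGCCCACTAACGGGCAAGGAACTTCCGTGATGATAGGCAATTACGTGCCGCCATGCCATGCACTATACAATAATTTGGGCATGGTGAAAGACAGTAGTGGTGTCCTATATAGAGCGATTCTACGAACATGTGCGAGA
>IGHV3-9*01
CGCACATCCTCCACACTCAATGACGACACTCGGAACTTCCGCCTCCTCTGTAACAGCATGCCTGCGATTGGCATCCAAACGGCGCGCATTCCAGCCAGTATCCACTTGCATTCAATTCCTTAAGTGACCGCGGGACTGCTTGGATTAGTAGATGCGTATGAACAGAAGCTAGCTCGAAGAGAGTTAGGTCGTTCCGACTGGAAGTTGCATAATAATATCGCGTCCACACTCACGGGTCTTCCTATGATCCGCGTAGTATGTGGGACTCGGGAACATATACTGACAAACTCCTGTGCGAGA
>IGHD1-26*01
TAGCATCCTGTAATATCA
>IGHD3-10*01
TTGATGTTGGCGTAAGCCGCGT
>IGHD6-19*01
CAAACCGTACCCGTGA
>IGHJ4*01
AGCCACCTGTTTGGTATGAATTCCTTGCGATCTTCT
>IGHJ6*01
CTATCGACCTGGGGTCGCCTATTAGTGCACAGCGTT
>IGKV1-39*01
CCAAGACGTTCTTTCGCTGGTAGTCTACGCAAATCACTTTGGAATGATCGCGCAATTTCGGCGTCCATGGGCTTCCCGGTGAGCAGGGCACACTTAGTCGATGTACGCTATGTGTGGGGGGTTCACGCCGTGCATAGCCCTCCAAGCTCGACCGTAGCGAGGAATCTCTGGCGAGCTTGTTTGGTAATTAGGGACCTGGAATGGACCCGACAGGTGGCTACCGGGCCGGAGATGATGTCTGTCCGAGATATACGCACGTTCCCAGTCATCTTAGGCCGAGCTCATTGGTCATGTGCGAGA
>IGKV1-5*01
ATCATGCTAAACATGAGGTCTTGGACTGATTACAGATGGAACACGTTACTCAGGCCGTCCAGCCGGGTATTGGACCCCCAGGCACATGTAGGTTTAGCGGTCATACTCTACTATCAATCACATCGGGAGAGATTTATGTCACATGTCCCTTGTCACGTTTCAACTTCGTCTGCCAGTGAACTCGTACTTACCCTAAAAGTCTTACTACCAACGGGTTTGGAGAAGATCTGGCGGTTTAGTTGGCTTACTGTGCGTTGGCAGAATGGCCGGGGACTCAACCCAGTAACCACTTGTGCGAGA
>IGKV3-20*01
TCCTATGCAGAGGAGGATAGAAGCCATCGCAACGTCTTCGCGGATTGTGACAGGTTTGCTCCAGGCATGCAGAACCAGAAGTTCGATAAAAGAAAGGTATGCTTATTCCGGTATTGGCCAGGCCAGGATCTATGTAACGCTACGTTCTACTCCAGGCGACTGATCTTGACTGATAAAAGGCCTGAGCTTGTGAGTGCCTTAGCTAATGAAAGAGCACCGAAGTGTATGTATGCGCTGACCACAACAAGACTCCGGCAAATCAGAGAGCTTAGCGCCCCCACCATGTTTGTGTGTGCGAGA
>IGKJ1*01
GGCCTACCATTCGGCAGACAAGTATCCGTGCCCATT
>IGKJ2*01
GCTTTGTACTTCGGGGGTGGAAAGTATACCTCTGCT
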