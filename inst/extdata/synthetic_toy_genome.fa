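>chrS synthetic toy genome
AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGA
ACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAAC
GTTCTAATAAACGACTTAGCAACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCT
CCCGCTTGCCGTCTTCAACTTCATGACCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCT
AGGCTTTGAAACAGCTGAATAAATCGTGTGAATACGTGAGTCGTCGGAAAGCAGTTGAAT
ATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCCAGTCCAGGCG
AGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTTTATCTATGCAGCTAATAT
CCTTAGTAGTCGACCCCTGAGATGACCGGTCATCAGGCGGCATCCGACGCACCAACGGCT
CCTACAGACTCGTGCTACCGGACCATGCGACTCGAACATCAGATGGACAGACCTCGTAAT
AGCCGGGCCATGTAACACTGATGTCTCCGGGCAGCTCATGACGAGCACCAGACCCGAGAG
TTCCTGTTAGTTTTGGTTAGGCACGGAACGCTATCGAGCGCGTAAGCGCCAACCCGCATT
TACGAAGTACCCATCGTATGTAATAAGACCTCGAGTACGTCGGGACGTTGGCTGTGATGT
TTTGATGAGCGAAGTTCGACGTTGCCGATGTTTACCCTAAGGGAGACGACATCATCGCAC
GACTCGTCATTTGCATCATCTCCACTGCCCCGATGTCTGCTATGGACGGCTTCACCTGAT
GTGGAGCGAGGGTACTGATAGATATACGACAATGCACGTAGTCTCGATACGTCATTGGTA
CGAACAGTTCGTATTCCCCATGTCTGGACCGACGTTAAGCTCATGTCTCAGGACGGAGAA
TGCAGCCCAACAGCTTGGCCGGATCAAGCAGGATGAGAGGCACTTACTTTCCCCGCTACG
ATGCTTTGCACAAATTCTACCGCATTGATCGTGGATTACTAGTTTTGATGGCATGGGTAA
TGGTGGAGCCAAACATCCAGCTAGCAGCTGCAAGCTTTGCCTACGTGGAGTCTCTGTGAA
ATTCAGAGATACGCAGCTAATGGCCCCGCTTAACGGGTGCATCGGCACAGCCTCGTGCAG
CCCTCACAAATTTCCGCCATCAGTGATTCAGTATTGTTTCACCGCAGTTACCGTGAAGTG
CCGCCATATACACAGGTTCATGCTAGAGAAACTGCCACCCGGGCTTGCCAACCGGCAACG
TGGCGTTGATTGACAGAGCTTCTTAAGCCGCTGATGTCCAAAAACTGAGTTAGTTCGAGA
TAGTTGGATGTCGCACTAGAGGGAACAGCCATAGGACCGATACAGACAGTTCAATGGCGG
ATGCCCGCACCTGTATACACCTAGTATGTAAAAATTGAATACGAGAGGGGCACCCTTTTG
CCCTCCCACTGTCTATTCCAGGTCGCCGAATATGTCCCGACTTCGACCCGTTTGGTAGGC
CAGGGGCCTGGGCTAAACACGGCCTTCCCGATTGCCATGAACTCGTTTCGCCTTAAAGTC
CAACCGTAAAGAAGCGACAGCGACCTAATCCGAGCTTTATCTTTTAAGCGGGCGCGGGGA
TGGAGTCTAAGGCACAGACGGATGCTCATCATATCTCGTAGCATTCATAATGTTGTGAAA
AACGGATAGGCTGGGTCAACAGATATGTGTGGTAGAATTACCGGCAGCTCTTTTGCCGGT
GGGTGCCCGGCGACCCGAAACTCGGATATGCATGGGGGAGGGCCACCCATTTATGTGCGA
GCTGGAAGACGGTTCAGCGGTCCCTCTTTGGATCGATTCCAAATGACTAACTACGAGACG
TGAGGCGTATAGAAACTTAGCGCCGTAGCAGAGGAATCAGGAGAGGCTGGTAAAACTAAG
TGTGAAGTATAAAATGCGGC
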