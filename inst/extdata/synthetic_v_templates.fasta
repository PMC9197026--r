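>synthV1 synthetic V-segment template
TTCAATCATAAAACGTTTAGCAATTGGCACCACCAATTGGCCTCCTCTTCTTCCCTGAGT
AAGACCCAACCGCCTGCGATTGGGGGTGTCTATGATGGGCCTGCGGCACTCGTACGATAG
TATACTCCATTAGCTACCATACTCATATTGCTGCACGCCCTTAATTTCCTTTCATCACCG
GGCAGTTTGTTCTTGGCATAGGGGCCCGAAAATAGGATACTAGGAGGTGTAATATATGTT
TTATCCTCGCGCAAGGGGCAGGATCCTCTCCATTACGCAGATTATATTCGGGGCAAGCAG
>synthV2 synthetic V-segment template
CACAGTCATATTGCTGCGCTCTCGTTTTCATAAAGTCGTGTATCTCACGCAGGTACACTT
GTATACACGTTTGGATCGAGTCGATGAATGATTCGTCGGATGGGAGTGGACAGTAGACCT
TCAATGGTACGCCGAGAGGTCACGGATAGACCCTACACCAGCTGCAATCTTGTTCAGCAG
GGGTCCGAGTAAGTAGCCTCTCAAATGCTGAGGTCTTAGACGTGATAGAATATCTCCATG
GGCGGCACTCAAACCGATCCAAGGCTCATCGACTCCTGACGGACCAACCCGCATATGGCC
>synthV3 synthetic V-segment template
TGGAAATTATGTACCGCACGTCACGGGTGAAAGCACGTTACGTCGTCTCCAGGAGAGTCC
TTTGTTTACACGAAATAAACCGGAGGCGATGCTCCTCACGTCAGGGATTTAATCAAGGTG
TTCTCAGGTATGGGATACGACCCTGGTCCTCGAGCGGTAACTCGTAAACAAGCTCGACTT
ATGGTAGGTAACTAGCGCACAGGTCGATCCACCCTGTGTCAAGCCCTAGGCAAATCATAG
CCGTCTACAGATTGAGCTAATCGCACGATGAGTATCAATCCCGACATGCATAGATGGAAT
>synthV4 synthetic V-segment template
GACAAGACCGATCGATACGATCTACTGCTGTTCCGGATGTGAGACACTGCTTCCAGTGAA
TATAGTGTCCGCCGTGTCCCATGATTTAGGCAGAGGGCATGCTGTTTCGGGTATAACCAC
ACACGGCACAAACAAACGCAGACTTCCAGCCGTACTGCTGCGAGCCAATTATGCGAAGAA
AGAGATCAAGACGCATACGTTCCCCGTAGGTCGCAGCCACGGGTAGTATATATAGTCGAC
GAGCACACACTTCACGACCGAGGACGCTTTTAATATTGATGGCTGGGGAGGTGCGGCTGG
>synthV5 synthetic V-segment template
GGTCTAATTGCAGTGATTCTGAGCCGAACCTGCATCCATCGGCGCCACCTGGATGAGGGC
GGCCCTCCTGCGAGAACGGCCTACGGCATGAGACAAGGCACTCTGCTGGTTGGGATGCGG
AAACTAGACTGACTGAAAATAACCGAGCCACAGAGCAACCTCCCCCAAACACATAGTATA
TTCGGATCCGGGCCCTCTGACGCGCCACCTATTACTGCTGGCGTCCGATCCAAATCCGCA
GAAGAGTCGCTAGAGCTCGGGGTCCCACGCAGGTCTCTCGCGAAACCGTCGTGCCAGAGC
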