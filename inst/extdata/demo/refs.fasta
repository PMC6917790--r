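>c1
AAGATTTCTTGTAGGAACGTACAACTGAGATAGTCACCATGGCAGAATATGGGACTTCGTTAATACGATC
CCCGCTCGTCTCGTATCCCGTCCAATGTTTTCCGAATTTCTAAGTTCGTAGGTTTGAACTATTAATACAT
CCGATACAGCTGAGTACCCTATTCTCGGCCTGGGGCATAAAAGGTTAACGCACCCCTCTTATAGCGAGGG
TTGCGATGTAGCTAGAGCCCGCGCAACATGCTCCTGCCGAGCGTCACTTTTCGATCACAACAGCAGGGGG
GCCAGCGCGCATGGGCATCCGATCCTGAACGCTTAACGGCGGCGTAGATAACCGTGTGAGGCAGCCAGAA
GTCCTGTAGGAGGCTTACCGGCGATATCCATGGGTACACCATTCTGAATCCTTGACAGCGCTCTCCGAGC
CGAATCGGTTTTGCACGCCGTAGAGGCATCGGTTGGGTAAGCACCTGCGAGCAAGGTACACTACAGACCC
AGAGGCAGCCCCTACATCAGCACGTGCGGTTCGCAATGGTCATGGCGAACTATCTATCGGACTCCCAGAA
ACCCGGTGTATCACCTCCTTCATTCGAAGTGAGAAGTGCGGGAGTGACGTGTTGAACCGGGTCTCTGGTG
GCCCTTCTATGCTATTGGAACAATTGCCGGAAGACATGAGGACGCCCGGGGATAGACCTTTCAACTTAAG
ATCTATCGGTAAGTATGGCTCTCGGAGGGTGAAACGGTTAATTAAGCAAGCCGCCGTCAAATCCTTAGGT
GCGCTCAAAATTGCTCGTGCAGTCTGGCACAACTTCTCGTCAGTTTACCTCTGCCACCCCCGCGTTGTAC
AACTTCGGACTAGGTCTAGAATGCGACCGGAACAGTCGATAATAACCCAAGGTGGAGCTTCCGCTAGCTC
GGAAAAATCCAAACTACGCGGAAAACCGCAGTCGAGCTTCGGGTGTTATTGTCACACCACGGTTCCGGTC
GCGAGCACGAACAACCTCGCACATGCTTCAGTCCCACGAGACGGCGGCAAACCCGTATGCAGGTTCTAAC
ACCTGATTCGCACCGTACGTTCGACTACCCGAGTTCATTCACATGTTCATCTTCGTAGAATGATCCAACA
TATGAATACGCTTCGTGCGTGAGTCCCGGCACAATAGTACTGGGCCCGTGCTAACCGAGAGCTCTAGGGA
TTGCATCCACAGTTGCGCCTAGGTTAAGCACTTGAATCATACGAATTGTCAGAAGATACATAGCTCTGGA
TTTCGTATAGGTCGTTCTGGAGGGCTTTCTCGCTACTGTGAAGCCATAAGCTGGGGCTATGGAATAAAAG
TCAATTCCTTAGTTGACGTTCTCGTCCGTCTACGAGGCACGTGGGCGCGACACCTGCTCGGACTCTGCTG
TCTGCCGTCGGGCGCGTCGAGGAAGAGCAAGAAAGTGACGTCATGTTATAATTGCACCCCTTGCTTGCGG
ACGAGGAGTACAATCTCACTTCGGGTTTGCCACAGTTGCGTCTCACTGTATGGTGGTTAAGAGTCACCTT
AACGGACTATGATGTTCGGTGAACCTCAAGGAGCTTGCACTCTCAGGCTGCACCCTTCCTATACTTGACT
GGGATAATTACAACAATGCGCCGCAACCAACTGCGCGAGGACCACTTGGAGATTGCAGCTCCTCGCACCA
AAGCCGGCTTCGCACAACAGCCTGGTCCTAGAAAGCAGGATTTCTGTAGCGTACACGAACTCGCTCGTTG
CTCTACAGCTCCACAACGCAATTTTCTGAGGCAGGGTTCGTAATGCACACAGGATTGCATCGTTTTTCCA
TATGACTCAACAGGTTTTCAATGACTTATAAGCAGACAATTAAGTAGTTACTTTAGCCCCCACCATTGCA
TACGGGACGCAAATCACTCATGAGACAAATAATGCACATCACATCGCTATCGCCTCACAGTTAATCGACC
AGGTACGTCGACTCATATATACGGGGATATTACAAGCCGA
>c2
TCAGTTGTACTAGATGAAAACCAATACGGTCACAAGGTAATCGATATAGATGACTTAGAGCGGTTTCGAG
TGCCCACAGTCCTGAAGAAAGGGTTATATAGGGTTAGCATATTTTCAGCTTATATCGTCAAAATGTAGGA
CTGCGCTCGCCCGCACGTGATCAAACACCTCCCGGCATATCTCCGAGTAGTATCCGTTCAAGTTAGCTCA
CGGTTCTCGCCCACGACACTGTATCGACACTCAATACAGATAAAGGGCTCGAGGCGGCGTGCCACGTTCT
GAACAGCTTACAATAATGAGGCGGACCGAGTTGAGGCTCCATCCAAGGAGCTCATGATATTGCTGTACAT
CGCTAAAGTCAGTAAGGTCTTCTAAGATGATCGATTCGCGATGATTTTTCCAGTTGCGCCTAGGTTAAGC
CACTCTAAAACAGTTGCGCCTAGGTTAAGCGCAGAGATGCGAACGAACCGCTATTAAATTGAGATACTTG
TGGGATACTCCTTAGCGGCAATTCGATGGCCTGATAAGAAGACGCACCTTGGATATCGCCGGTAAGCCTA
CAGCTCATGTCTACTAAAATGTTAAACCCATAACCCGCCGACGGGGTCGAGGAGTTGGATCCTCATTCTG
CATTTTAGAGGGTGGAAGCAGATACCCCCGATGTGACAAACGAGCTTACACAGCTGAGAAGGCGTCGTGT
AGCAATCGTGCAAGGTTCCTAGGTTCATATATCCTTTATGGTTATCCAGATGGCAAAGGTAATCGCTCTC
AGTTCATGGGTTTGGCTGACTTGACGAGACCGTCATCTAAGCAACTATAAATATGCTCACCCAAGATCTA
ATCTTTCCATATATAGCCAAGCAATATAGAGTTTCTATAATAAGTAGTTCTAGTTGTTTACGTTGCATAT
TTATGGAATCATGGTGCCCAGATTTATGCTCAAAGCACAAATTGGGGTAATGCGTCTTGCTATCACCACA
TCCCGTAACTGCACGGAAGCGTGTGACCTTTTTGTCCGCCAGTTACATCGGGCGGAACGATAACCTATCT
GCAACGAATAGTTTTTTTAAGGTACCGACCAAAGCACCTTTCTACTGTCGCGGAAGTGACAACACGCTAA
TCGCCATCAACTGTCGTGATAGGGGATACCCGTGTCAAAAGGCTTGCCTCCAGGACAAGTATGTGTACCT
TAAATAGTCCTTCTTATTTTGAAAGCCGAGTTTATCCGCCCAGAAGTTCTCTAAGCGTGGACTCAGACAA
GCAGTTTTTGGTGGGAGAACCCGAAATGCCGGCGTCGTCCGACCCTGTGGCTTCTGTCTGGGCGCACGTA
GACAGGAAAAAAAAGAAACCTAACTCGATGTCCCCATTAGCCGGTGGCACTCTCCGGGGGGGCGTACAGC
AGCTCACTCGGTTTTAGTCTCCCTGTGTGGCTACGAGGCTGATGATGTTGAAAATAACATTTAAAATTCT
TAAGCCACAAATCCTGATTCACCACCTTATGAAATACAACCCTGGCTCGCATAACTCACTACGCAACACC
AAGGAGACCTGCAACGTGTCATCCGAAAATTGATATTTAGAAATGATATTCTATTATCATAATTGTGGGG
AAGATTTCTCGTCAACGTAGTGTTCTATTAAAGATCATTCTAACTACTACTTAACGTAAAGTCAAGAAGA
TACCCAGGTATTTCATCAAACTCTATAGATGAAGATCTTAGCGTCATCCATTTCGAAAAATTTGCCGTGG
TTGAATGATGTATGCTCCTGATCTGCAGGGTCAGACAGATTTTTACTTTT
>c3
TGGTCCGCCGCCACGCCGCGTGGGCGCTGATTACCTAGAGGGTGCGCGGGCCGTATAGTCGGAGAACTTA
TCGGGGGCGAGTGCGCAGAAGCGTGGAACGCTTACGCTACAGTCCTGCCTACCGCCAAAGCGGCTGGCAT
TACACCGATACGGGGTCTACTCTACACTTGTGCGCTTTTGACAGCATGCAGTCTGGTAGAGCACCCTTCT
AGGAGTGAATGGGGCTCCTCCTGTAAGCATGTTATGAGGACGTAGGCCATATTCGACTGCCCCACTAGGG
AGTTCGGGCGGCACAACAACGTGCTACCCGGATTCGAGTTGTCGCCGCTGGTTGGGGGGAGTAACTTCTG
GGGGCTAGCCCTTTCTGCGGCCCCACACAGTGCCTCCCAATAGAGGCAGGCACTTTGCACTTTGAGGCTC
GCCCCCAGGCTCTATCCCGATAAGCGGGCTGCAAGCTTAACGCCATGGACCGTCATTTAATGCAGATGGA
CAGGGAACGTAGCCGGTGCGGAACAATAACGGCGTCACTGAACAATGCCGACATCCTGAGCATACTCGTG
TCTATCGTCACCACGGCCTCCCCATAGCAGTTCCGCCGTGGTACCGCCGCTCGGGGGCCCCGTGCTAGTG
GGCAACCCGTATTACCCACGGCGGAAGCGCTCACGCGCTAATACCGTAGAGAAATTCAAGTAACATGGTG
GCCCAACCTTCCCGCTTGCGAACTCTAACGATTGGGGAACGCTTTCATCCTCGAGTGATCACGCCGCCAT
CTCCAATCAGCTTTAAACCGCCGGGTAATTTCGCAATGGTCATGCCGAATCCATGCTGCAGCCAGTAGAG
GTGCAAGAAAACACATGCCGTCCGCACGTGATTCTACGTCGCAGCTATACGAATGACTGGGAGAGGGATG
CTCGGCGTGATGAAGACTGCTTCGATCCCTGCTTCGGGTCCTCATCGGTTTCGAGCGCCCATTGTTTTGT
CTGGGCCGGCTTGCCTTCACAGGCGCAAGGCTCTTCGTGGGAATCATGTCATGCCTAGAAGAGGTATAGG
AATGCCCGGTTGTGTCCCGAATGGCTAGCCGGATCCTGGCGCTATGCGACCTTAGCGGCAATTCGATGGT
CGAATCCGCGCCCCATTAGCTACGGCTTGAGGTGATTCCGTCTTCCACTCCTCACTACTGAGGGAAGATT
GGAGCGTAGATATACCAAGACATTCGTTAAACAATGCGACAAATTATATCCACTGGTGAGCTGTACTTCC
GTTGATGAGCATGGTGGCATCCAACGCACTCGTTGTCCCCCCGGTAACGACCCGCAGACACAATGGGCCC
ATGACTGGTGTTCACGTAGAATGTAGGGTGCCGGCGTAACGTCTTCCGGTGACCTCTGACCACTGAGGCC
AAGACGTGATCTAATGTCGTAACTCAATATTGCTGGCTGTTAGCACGGATTTCAAGTATCTATAACAGTG
TCGTGCTTCAACCCCCCATTGGGGAACCGT
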