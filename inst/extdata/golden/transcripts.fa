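>PARA1
TGCAGCGACGCTACCGATTGATCAGGACCTAGAATGCTGAGTGGTTATTAATGCCGCAAAACAACCATGGAATCGTTCTCTGTGATGATTAGTTTGTCGTCGTACTTCCTAATTGTCCAGAGAAGACGCGGGTGCGGCCTCCTGAAGAGGTACATACCCTGTTTTGAACACGGGCGACTCACGCTCTTCTCCAGACTTTTTGCCAAGGTCAACATCGGTCAATCCATGAGTGCCAAATGTAGCATTGGGTTGCAGCCCCAGATCTCACTCTACGCTATAAAGGGTCGATTATGCTGCCTTTTATAGGTTATTCTCCTCGGGAGGATGATTAGGTACGTACGCTAAATCAGAGCCATGAGCGGTAAGACCCGCACAATCTCATGCGTACTATGACTCCTGACGCGCCGACCTCTAGTCTTCGTGGAACCTTCAAACCAGTGTTATGCTGTAATGTACTCTAACTCATAAGTTTAAGCAAACATGTGGTGGTATCCTAGATATAGCTTAAAAGAACATAACCACCCCTCTTTAGTTGGGGAACTTAGCTTCAGGGTGACGATCTCGCGGCGTACTCCATATCTTCGGTTTGCTCAGAGCGGTGATCGACCCCCTAAAAACCCCAGAGGAGGAAGGAAGATAACAAGATCATTGATGTGTATCTTCCAAATAAAACGTGCGGAATTGGGCAACAACACAGTAAGTTTTCAATAGATTACCCGAACAGGACGATCCCGGTCTACCGGTTTTGGTGAGTGTTTTCTACTTATTATAACATAGTGGGAAAAAGCTGTCAGAAAAAA
>PARA2
TTTCATGTCTACAAGTCCCCGATGGTGCCTTAATAATACTAAGATCATCTCCCTCAGCATCTCAAACCTGGCCTCAAAAAGGAGACGACATATTCCGGCACCATGCCGGCTTCTTGACTATATGCTTCGTGAGAATAGTAGGTGCAGGGGCGAGGCTTTATGTTCGTCCATCGGCCTTCGAATAGAATGTTCTGTTTGTGATCGTCGAGACCCTACCGGAATTGAGATTAAAAACAGTTATATTATTGATCGCCATCTGGGTCTCGACCTCTTTTAGAGTTTAAAAATTGTCTGAGCCCAACAAAACAGCACGTGGGTACGTGCTTTTGGTGCCAAGGTCAACATCGGTCAATCCATGAGTGCCAAATGTAGCACCAGATGATGAAGCCTATTGTGTGTGAGAAGTGCAAGCTGATTGAGCGAGGAACCCGTGGTGCAGTTGTGACAATATTTTGGGCCAGTTAGCTTGGTGGTTAGTCTCGTTTTCAGCGAATTGGTTTGACGAGGCCGAGCGTTCATGGGGGTGCTAATATTACCAAGTGCTGTAAAAAGGAGAATAATAAAATAAAATTTTTGGTTTCCCATGTCGAGCCGATACACGACCTATATGATAAGGGGTAATATCTTCTTTTACGGTCATGAACATACAGGGAGGGGAGATTCGTGCTGTATTAAAAGTATTCACTCCTTTGTATCGTCAGGAAGGAAAATCGTTAAGCCGACAAGATAGTCAGAGCGTACAGCGCCTTGTTTGTATCCGAAAGCACTCGCCGTCTAGATTAGTGGACATATAGGCACGC
>PARA3
AACGACGTCTTGGCACCGCATTTACACTACTAACGTCGCGCTACTTCGCTTTGTACTTTCACACCGCTATCTATAATGGCGGACCATACCTGAAGTATTCCCTTCCCAATACAGGATTTACTCATCTTAACTCGGGGAGTCTTAATTCCTTGCCAAGGTCAACATCGGTCAATCCATGAGTGCCAAATGTAGTTTCTACCTGTGTTTTGTAAAGACACATCGCATTTGGGACAGTTCTTCCAGTTTTTGAGCGCAATGCTACAAAAACTTTTCGAAGTATTATCACTATATTTTTAGTTACATTCTATATGCGAAGTCAAGGGGGCACCCGAATGCAGACCTGTATAGAGTATTCCGGCCCCTTCGAAAGTTACGCGAATAGCGTGTCGTAAATGGTCTGATAGCACCTGGTTTTTATCCCATAATAGCCAAGCTGTAAGTGCCGTAACGAGAGTCTTAGTGACACATGTGCCCTGAACACGTACCCTCCCACGGCACCCACTCTCCCGTCGTGCGAACTCAATTATAACAATCTTTTGGCCAGCGAGTGTAAGGTAGGATGATCATGTATAGTCATTATAGACTACCAAGAACTGCCTAAATGGGATCCCCTGAGAGTAACTCCGTAACTCACGACCTGGTTGTATGATTACGCTACGATTAAGAAATCCCCATAAGCAAACGCAACGGACTAGGGGCTTTCATTACTGTATACGGAGCTCGACCTACAGGTGCGGTGGCCACCTTCTTCACATCTAGGTGGGAAAGGCAGGCTCCCTCTGCGACCCAGGAATCAGCGT
>TASL1
CACTATACGACAACATCCGAGGCAAATACATACCACGCGATTTACCTCCAATGAACATAGGGTGATCGAATTCCTTCGAGGTCATTAAATATCGTGATCAACCTTTAACGTGACTCCTGAAACTACTCTACATCGTCTCTAAGCTGGGCGGTAGTTTTGAATGGATGATAGAGCTGAGTCTATTGCCATGGCGGTCGTATTCGAGGGATAACGAGGACATCAGCTGGTTATGGCACTTCCACCCATGATCAAAGAAGGTTGACATGTTACTATAGTCTGTCGTAGATTTTCCTTATTCCACGCATAATGATTTTTAGAAACTAATTAATTAAGTCTCACGACCGCCATGGCAATAGACTCAGGATTAGAAACCTCACATAGTATCCTACGAGGTACCGTG
>ARFL1
TGTTCGTCCTGAGCGCCATTAGTACTGCAATCTATCGATCAGCTACCACTGCCTCAACACAAATAGCGTTAAACTTCCTAACTCACAAATTCCAAAAATTACAGCCGGTAACAATGCAGTCAATAAACTTACCTATGCCGTGAAAAGCAAGTTCAACTTGAACTTTGTGCTCAGAAATGCATGAAGCTGGAAAGATGATTAGCTGATCCTAATAGGCGTCCGAAGTTATGGCTCGGGATTCTTGAGATCGCTTAGGAATCAAAGGCTACCTGTCAGGTTAAGACTGCATGGAGCAATATGGACCGCCATGGCAATAGACTCCCGGGTAGGGGGACTGACAACTGGGTTTGTCCCATGAACCGGCTGTCGGATATTTCGTATTTCAGTGTTCTCCCCTCCTTCCTTACACAAGTTATTAGATTATAACCTACTTGGCTTTCCGTGTCAGAGTCAGAAAATGGGTCAACCATAGAAATCTATGGCAGGGAACGCCTTGACCATGGGCAAGAACATGCTACATGAGATCTAACTCAATACGATGGGAAGGTTTACCCAGATACTAATGGAGCCCAAACGGCGTCATATCGCACCACGGATAGT
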