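>deg1_x1
AAACGTGCGGAATTGGGCAAC
>deg2_x1
AACAAGATCATTGATGTGTAT
>deg3_x1
AACCAGTGTTATGCTGTAATG
>deg4_x1
AAGATAACAAGATCATTGATG
>deg5_x1
ACAATCTCATGCGTACTATG
>deg6_x90
ACATCGGTCAATCCATGAGT
>deg7_x1
ACCTAGAATGCTGAGTGGTTA
>deg8_x1
ACGATTAAGAAATCCCCATAA
>deg9_x1
ACTAAGATCATCTCCCTCAG
>deg10_x1
ACTTATTATAACATAGTGGGA
>deg11_x1
AGAGTCTTAGTGACACATGTG
>deg12_x1
AGGTGCGGTGGCCACCTTCT
>deg13_x1
AGTTTTCAATAGATTACCCG
>deg14_x1
ATACCTGAAGTATTCCCTTC
>deg15_x1
ATCGTCGAGACCCTACCGGAA
>deg16_x1
ATGATTACGCTACGATTAAGA
>deg17_x1
ATGCAGTCAATAAACTTACCT
>deg18_x1
ATGGAGCCCAAACGGCGTCAT
>deg19_x1
ATGGCTCGGGATTCTTGAGAT
>deg20_x1
CAAAGGCTACCTGTCAGGTTA
>deg21_x1
CAACCTTTAACGTGACTCCT
>deg22_x30
CAATAGACTCAGGATTAGAA
>deg23_x30
CAATAGACTCCCGGGTAGGG
>deg24_x1
CTAAGATCATCTCCCTCAGC
>deg25_x1
CTCTGTGATGATTAGTTTGT
>deg26_x1
CTTCCTAACTCACAAATTCCA
>deg27_x30
GACTCCTGAAACTACTCTACA
>deg28_x1
GATTACGCTACGATTAAGAA
>deg29_x1
GATTTACCTCCAATGAACATA
>deg30_x1
GCAAGCTGATTGAGCGAGGA
>deg31_x1
GGAACCCGTGGTGCAGTTGTG
>deg32_x1
GTTCTTCCAGTTTTTGAGCGC
>deg33_x1
TAAAAACCCCAGAGGAGGAAG
>deg34_x1
TAAAAGTATTCACTCCTTTG
>deg35_x1
TAATAATACTAAGATCATCT
>deg36_x1
TACCCGAACAGGACGATCCC
>deg37_x1
TATCGTGATCAACCTTTAAC
>deg38_x1
TATGCGAAGTCAAGGGGGCA
>deg39_x1
TCAAAGGCTACCTGTCAGGTT
>deg40_x1
TCAGAAAATGGGTCAACCAT
>deg41_x1
TCCGGCCCCTTCGAAAGTTA
>deg42_x1
TGGGCAACAACACAGTAAGTT
>deg43_x1
TGTATAGTCATTATAGACTA
>deg44_x1
TTAGGTACGTACGCTAAATC
>deg45_x1
TTAGTACTGCAATCTATCGAT
>deg46_x1
TTATTAGATTATAACCTACT
>deg47_x1
TTCCAAAAATTACAGCCGGTA
>deg48_x1
TTGTGTGTGAGAAGTGCAAG
>deg49_x1
TTTAGAAACTAATTAATTAA
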