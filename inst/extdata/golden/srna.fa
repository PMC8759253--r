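>sr1_x5
ACTCCTGAAACTACTCTACAT
>sr2_x5
AGACTATAGTAACATGTCAAC
>sr3_x1
ATGATAGAGCTGAGTCTATTG
>sr4_x1
CACCCATGATCAAAGAAGGTT
>sr5_x5
CATCAGCTGGTTATGGCACTT
>sr6_x5
CCACCCATGATCAAAGAAGGT
>sr7_x5
CCGCCATGGCAATAGACTCAG
>sr8_x5
CGTAGATTTTCCTTATTCCAC
>sr9_x5
CGTCTCTAAGCTGGGCGGTAG
>sr10_x1
CTGGTTATGGCACTTCCACCC
>sr11_x5
GAGTCTATTGCCATGGCGGTC
>sr12_x1
GCGGTAGTTTTGAATGGATGA
>sr13_x5
GTATTCGAGGGATAACGAGGA
>sr14_x1
TCCACCCATGATCAAAGAAGG
>sr15_x5
TGACATGTTACTATAGTCTGT
>sr16_x1
TGGGCGGTAGTTTTGAATGGA
>sr17_x5
TTTTGAATGGATGATAGAGCT
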