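GACTTGTC
GGGTGGCG
CCTAGTCG
CGGCCAAA
ATCACACA
GCCCATAC
TGCGCTGG
AATTACAA
TGGCCTCA
TGCAGCCC
GTGGCAGA
GAAGGGCA
CGCCCCTG
AGAACCCT
CAGTTGTG
AGGGTATC
TCAGTGAT
TAAGACCG
ATCATTGG
CGGTCCAG
ACTCTATG
TTACAGAG
AATCACGT
TACATGCC
AATTATGG
GTCTCCGC
TGTCAAGC
GTTAGCAC
AGACGTCG
CAAAACCA
GGTTGAAA
TATACATA
CTAGCCCG
TTTTACAC
GGTGGATC
ATGTGACA
GACCCCGG
CCACATCG
CGAGAAAT
CCGTAACT
CTCAGCAT
GGTTCCCT
GCTGTCTT
TGTGGTCA
GTTTCGAC
TTACCGGA
CCTTTAGG
AAACATTC
AACCTACA
ACGCCTTC
CCTCCTTA
TAATTTCT
GGAGGGAG
ATAGGGGC
CTCGAACA
CGGGAAGC
ATCGAAAC
ACGATACG
TCCTGTTC
TAGGAAAG
ATCGCGGA
GTCGTGGG
AGTTAATA
GTTCGTCA
GATATATT
CGAATGTA
GCCACTAT
AATGGCCG
CCCAGAAG
CACCGACG
GTTAAACC
AATATTAC
ATTCGATT
GAGGCCAG
CTCCACGT
TGATAGTA
TCATGCGT
CGCCGCCT
ATACTGCC
GATTCGTG
CTTGTTGC
CTTGTGCG
GCACGGGC
AAAGCGAT
TCAGCGCC
AAGGATTG
TTTGCCTT
TGCGGATG
TTTTGATG
GCAGTCAA
TGATCTAA
CGCAAAAA
GCTCGTAG
AGCGCTCT
AACACAAT
CTCGGCGA
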