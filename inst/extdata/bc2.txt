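GACGTGGT
TGCTACAC
TGTCACTA
AACCGCTC
CGGCCAAA
CGGGAGAT
GGATGACG
TCGAAGGG
AGTGTATT
AGCGGATA
TCATAGGT
GTACCTAG
ACGACAAG
GAGTACCA
ACGTTTGG
TCGTCCTG
ATCAGGAG
CCAGACTA
CCCTCTCG
AGCTTTGA
GCTACTGT
CTGGACAA
TTTCGCTT
AAGAGCCC
ATTTGAGG
CACCGGCT
GGAACTAC
ACAAACGA
ACACGAGG
CCTGTATG
TCAGTCCA
CTTAACTG
TCACTTTC
TAGTATGG
GTAGTTAC
TCGAAAAA
CTAAACGC
AGCACATT
ATCCGTAA
CACATCGG
CATCGTAT
TAGGAGAA
CAAGGATC
TGCGGAGG
TGGCGAGT
CTGCAGTA
CAGTGGCC
AGCGATTT
CATAAGAT
ACACCCTT
TGCCCCCA
ATAGTCAA
CCGGGTGT
AAACACAA
GGTTAATG
AATAATTT
AGTCCTTC
GATACGCG
TTGAAAGT
CACGTAAG
TTCCATTC
TCTACCGC
TGGTGGTA
GCAAGACC
ATCATTCG
AATAGCTG
GCAACATA
CCCATGCA
GACATACA
TTCACACT
CATTGTCG
ACTCGTGA
CTGCGACC
TACAAGCA
GAGGCTGG
AGTTGATC
ACAGATGG
ATTGCGTT
CAGTCTTG
ATATACGG
ATCCGATT
ATCTTAAT
TACTGAAC
CCCCGCGG
CTTCCAAC
CCTTTTCC
TAGTACTC
CATGGACT
GAGTGGGT
TTGACGGA
ATCTCCTA
GCCGCGTC
GGGACGGC
ATGTTGCG
GCAGACGC
ATGGGACA
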