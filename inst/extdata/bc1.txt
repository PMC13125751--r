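TTGCGTGC
GCAACGGC
CTGTTCAA
TCGTGGCG
CACGGCAC
ACTCACGT
CCATTTTA
CCTGGGAT
TGCGATAA
TGGCCACT
GGATGCGT
GTATTACT
CTTCAACA
CCTAATCT
GAAGAAGT
GCATATAA
TTCGTCGG
TCTCGTAG
TTACGACG
CCAACATG
GCACCACC
CGACCTCT
ATGCCAGG
ACTGTTAC
CGGTGAAG
GAGAGTGT
AAGACCAA
ATGTGACT
TCGTTCGC
TTGGGTCA
CTAATGAT
TCTACCCA
TACCGTAT
TCTTGATA
GCGCAGAC
TTCCTACT
GTGGCAAA
CCCCCCAC
TCGCTGAT
GTATTTGC
GGCAGGTA
AGTTGTCA
TTAAGGGG
ATCCCTAT
CTGCTTGA
TAAAGCTA
TCTCGCTC
ACGGGGGT
TTCGAGCA
TAGAAGCA
ATTGTGAT
GCTGACTG
CGATGGAC
ATCTTTTC
AGATTCGG
ATTAGATA
TTATTGAC
CACGGGCA
GCACAAGA
ACGATATC
TGTCGTCT
CGAGGAAT
GGGGCCGA
AATTATTA
TAAGCCGT
TTAGTGGA
TAGTAAGT
CTACGTAG
AATTTGGT
GCGGGTTA
TATAGGAT
ACGTAAAC
AAAACAGC
GATCAGCG
GCACGGAT
AGCTTGCC
ACCGCCCC
GGTTTGTC
AAGTTTAA
TCCAGAAT
GCCCAGCA
CGGACCCT
GGTTCCAT
TCACCGAG
GAATAGCC
TAAATCGC
GGTGGAAG
GAACACTC
CCCCAGAG
TGAGATGC
ACGGTCTT
TCGCGAGT
GCCCTGTG
TACGCGTC
CCGCGCGA
AGCCGAAA
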