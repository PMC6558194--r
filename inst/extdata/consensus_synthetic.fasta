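>IGHG1|CH1 synthetic consensus
CATGTGGTAAGACTTTTGCCCTGTAAGCTGGCCGTGGTGAAGTTCGTGAGAAACAATGGC
CATTATGGACTACCGAGGTGTAATGGGGAGAAATCCCTCATGGAAGTCAACCGAGCATGG
GAACACAGCTACGGTATAACTGGTGCTAAAGAGGGCACGAATAAAGTGGACCTCCAATAC
AGGAAAGACGGCATTCCTCCGTGTGCCGTCACGTTTTATTACGACGGAGGTTGCCCCTCG
GGCTACAGTAGATGTAAAGGGCGGTTTCCACAACTGGATGTTCACTGTACCCTT
>IGHG1|CH2 synthetic consensus
ACTGACTACTTGTCGTCTGCTGCCGTGCGATCCTATTCAAAGCGGCGCACCCCACGTCCA
CCAAAAGATTTCGGGTATATTCCAGCCAATGCATCGTATCTTGACACTCTACGGTCTCTC
CCGGGCTTGCAAGCATTGCTGTGGAGTTATTTAACCATGCAGCTCCCGATCCGGCCCTCC
CCGCACGGCGCATGTACGGTACGAACACAATCGAGGACGCGGCTCTACACAGCCCAACTC
TCTGCTGACGTGCTTAAGTCTCTTCCGCTCGTTGGCGATGCCCCAACGATCTGTTCTTAT
GGGGTGTCACGTACGCCGAAGATATTTAAT
>IGHG1|CH3 synthetic consensus
CAGTTCGCCCCGCCGTCTGGCGCCACTCTAACCAAACGCTACGCCCTTGTCACGTTCACG
GACCAGGAATCTTATCTTCGGGAATTACGCAGACAACCCGGATCACACGGAGCTGTTACC
GTTTCGGTAACTGAATGTTATCCGCAGACTAACCAAGGAGCGGTCCGAATTGTGATGCAC
CAAATCTTAGGTCACCATCCCTTTATAAACCTCCCATCTCCGCTTCGTTACGCCATAGTC
ACGTGGGCGTTCGCAAATTCGATACACAAGCTAGGCAGCGTCCTACACTGTACACATCTC
GCTAGAGGCCTTCCGAGGCTC
>IGHG2|CH1 synthetic consensus
TATACCCAACCGTTCAAAGCGGGACGATACCGTATCTCAGTCAGGGGGCTCCATCCCACA
CCAATAACTTCTAACCTCTCGAAGCATAGGAGTTACAACTACGAGTCCCAGCGGAGATAC
TTCAGATACTGCCTTCCGGTGCAGTCCAGCCAATTCCAGGACCGATTGATGTGTCGCAGG
CGAGATCTAGGAGACATTAGAACTCCGATAGGCAGTCTATGGAAGCCGAATCCTAATTCT
GCACTCCTGGTTCTTCGACATACCGTCAACGCTGTGTTTTGGAATTATTGGAAG
>IGHG2|CH2 synthetic consensus
GAAGTCTGTTCTAGCATGTCATCATATGCTTATCTAGAGCGGCCAAACTTTTGTTGGGTA
TACCCGCCGGTAACGCACAATGTGACGGAGGATAACTTTTCATGTACAAGGGCAGTCACC
AAGTCTTTGCACGTTTGTTTATACAATGAGGTTCGAGCTACGGCCGTGAACCAGGGAACC
TGTATTTTTTTCATCTCGGCATTATTTTCCGAGACACCCTTATATTACCTGCAACTTCAG
CCGGTTCAGAGACAACGACATAGAAGCGAGTGTGGCTACGGGATTGACTATGACCCTCAA
ACAATCCTTTGGGCTTTGCAAAGCGTCTAT
>IGHG2|CH3 synthetic consensus
CATGTTAAAGGCGCGATCTCAACGAACTGCCGCTATAACAAGCAAGCCCTTTTTGAAATT
GATACATGGGATGGGAGCTGTCTAGTGACTACACCAAGGAAACGCCGCTCGTTGCCCGTA
GATGGATTGTCGCCTGCTGGCAGAATCTTTTGCGGTGAAAAAGGTTTCTACTTTTACATC
TGCGTCGCAAGTCTACTTGCTTTGCGAAGCGGTGATGAGATAGCGGCGGCACGTTCATTT
TTAGGAGGCGACCTGCCCCGGGAGCTAAGTGTTACATGTGCGACCAATTGGCCATGGGGT
CATGACGAATGTTACCGTGCC
>IGHG3|CH1 synthetic consensus
ATCACGCCTTGGCTGATCCAGTTTGGGCACTCCCGCTGCTACCGATTTGGTGTAAGGCGA
AGTCATGTTGAATTAGGTCTCGTCCACTGGGGTCTTATTTCTCTCAGTGCACTGACGTGT
TGCCTGAGAGTACCGAGCACATGGCGCTGGGCGCCCACGAGATTTCTGGTTTGGCGGCTC
GCGTGCGAGCTCAAAGAATCACCGTATCAGTGTTGCCACCTGGTCAGGTTACCACTCTTC
CTCAACAACCACAGGATGCCGGGTCCGGAATATTTAGCGCGCGAAGTCGCCCGC
>IGHG3|H1 synthetic consensus
TTCATACTGCCCGGTCCACTTCCCGGCTACCCGGACTGGATTACGTGGAAA
>IGHG3|H2 synthetic consensus
ACTGGAATCTCAATAGGTGACGAAGATAGACTTATCCCGAGCGAT
>IGHG3|H3 synthetic consensus
CCTCACGCATGCCTACCGAATGTTAATCTCGTTCAAGTGTGCGGG
>IGHG3|H4 synthetic consensus
CCCGATTGTGTGTCAGCGGCTCTGGCTTGGGCTAAATGGGAATAT
>IGHG3|CH2 synthetic consensus
AGCTTGGATCAGCAAACCTCTGGATGGCTGGTCCGAAGCTTGCAATGGCGGGGCACCCGT
TACTTGTATAGCCATTTGCTCCATGCCGCGTTATTACGCAGGAAATCGCTGAATAGACCT
TCCTATCTCAAGCGCACTACTCAGCGTCACTATTACGACTCAATATTGCACTTTAAACGT
CACAGCATAACTCCTACATCGGGTACCAACACAGTTGCTCTTTCGTATGTGCTCCCCATT
AGAGGTCGACCCAGTAAAATGTCGTTTCCGGTTAACACCCGGATAATGCGTGATCCCTGG
TTTGCACCATCTCCCGTGCGGCCACTAAGG
>IGHG3|CH3 synthetic consensus
AAGCAGCTTACCGGACTCTTGGGAAGGGAGTATCGGTCATCATGGAGCTGCAGCAACGTA
GCTTATTTGACTTTATGTCGAGCGTTCATTCGCGATACTCGTTTGGTCTTCGCGGGTCCG
GAGGGTGACGCGAAGCCACTCGGTGCCCGTGGACCGATCCGTAGTACATCTCTTGCCAAG
GACGTCAGTCTGTATCTTAGCAACACTTCACCTCCATGGGAAAAGGGAGGCCCCTTAACT
CCATGGGCAGTGATCCCAGGTATCGGGGAGTGTTCATATGGCGGATGCCGGAGTTGCGTG
CTCATTTATTGTGTGAACGGA
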