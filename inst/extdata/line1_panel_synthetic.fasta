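>P1
ATTAACTCTACGGCACAAGTGTTCTCGTCGACCCAGTCTTCCGTCATATGACTATTCCGTTGGATTCATAATCAAGCGCGACCCCCATAGTACGGAGCCATGATCTAGCGTATCAGAGTA
>P2
GCACTTATAGCATTGCTTTTATAGCCGGACTAATCTCTCGTGATCGGATTGTCGTTGAATGGCCAGCGGCGGCATCGAAACCTCGATTCAAATGACCCATCCGAACCACTACCGGGTACTCTATCACACCAA
>P3
CTTGCAAATCGACTCATGTTGGGAACCGCTTTATCGACTCACGTCGGTATTCCATGACCTGCGCACCGAACCTTGTTGATCGACTCGACTACTTATAAAATCATAGATTA
>P4
AAGGATAGTCGCCAATTAAAGAAGTTAACTCGTCGCCTGCTCTTAACCGGATTTTCTAGCGTGCGGCTGAAATGCCACTCGCATAGATAGTAGTCCCGACCGCATGACGTGACATGTAGGATATAA
>P5
TAACCGTCACTACCAGAGGTCCAACATCGCTAACATCGCTCGACGACACAAGAATAATCGACACCCACTATTAGGCCCGTGACAGCAACTCGCCTTAGCAATCACGCACTCAAGATTT
>P6
CACATTATCTCATCCTAGACAATACCGCCCGGCTATGATCTTAACCGGTGTGGTCAACAGCCCGTAGATGGATTAGATAGCCGTTATAGCACTAACTCGTAATTTACATCGAGAAATATAAAAT
>P7
TATTGCAAAAACACGAGCGAGCACTGCGTCCTGTAGTCCAACCCGGGTTGCATGAGCATGCGCTCGAAGACCCAAACTCGTAGAAAAGCTGTAAAGTAGAATTTAAACACGATA
>P8
CTCGACAGCACTGCAATTCATCGCCTTAGTCGGAGATGTACATTACGGCCTCCGTGGTTGGTCCACACCTCTGCCGTCGGTTGCATGCCAGATGTGCCATGGTATTGGATGACGGAGTCCTTATGCTG
>P9
ATATGCGCACGTAAGTTACATTTCGACACGACCATGGCCAACCGGTATGCGAGGGAATTTCATTCACTCTCCGTGGTCAACTCACATCCCTGCGCTCAAGCTTGCTCGGTGTAGCCTGGCCT
>P10
CAATTCAGACATAATCTAGAGCCCTAGCGTCGAAAGGCAGAACACACTCGCCGAAGAGCAACCCAGTTTCGCCAAGCGGACAACGACGCTAGTCCTTCTCGGGTTCAATAATTACG
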