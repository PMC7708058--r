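>synthetic_cI synthetic 714-nt reporter gene (randomly generated stand-in)
ATGGACGCGCAGCCTTACACCTGGCCTCGTCTTCATTAAGCCGAGGCAGGAGCGACTTTA
GACACTCATCCGTCGTGCCTTATTTATTTTCCAGAATAGAATGCGTATCGTTATAGCGGT
CATATCCTCATTGTACCTGCTCTTGCCACCACCGAAAATTTGAAACTAAACATCCCGATG
CAGTACCTAGCTAACGGCAAGCCCAATCGATACATCAGACGGTAGTACCCTACAAAGGGT
GGAGCATCCTCACCCCACGATCTGCCTGCAAATGAAGAGCATTTGGAAATACTCTAGTGG
ACTGAGAAGACTTGACGCCGACTATCTTGCTCGGCTGCTTACACCCCACGCACCTGGAAC
TACAAGGAGAATGTCTCCTCTTGACGGCAGTTAGGCCTCCTCTACAAGTACACTCCGAGA
CATGCGGCTCTCGAGAGGACCAAGTATATGGTGCAGAATAACAATCCTGAACACCGTTCA
TGCTACACCATCTCAGAATGCTTGATCGAGAAGACCAAGTTTAAGTCCCTTTTCGTCACC
TTCCTTGACCGGTGTTCTTCTTGCGATGATTCGCTTTGTCGCCCCACGGTACCTACTTAG
CTGTACACGATCGGGACGGGATATCGTACTGTCGACATGAAACCCCATGATAGATCCGGC
CCGTAGCGTGTAAAGAACAATGTGGGACGATCCATGGTGGCAAAACCAAAAAAT
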