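# Artificial half R-loop substrate components (synthetic assay design).
# rna: in-vitro-transcribed RNA forming the RNA:DNA hybrid
# primer: cDNA-synthesis primer extending the duplex segment
# oligo: paired DNA oligo completing the double-stranded segment
rna	GGGAUGGUGCUGGACUCAUUCGGCAUCGGCGCUACAGAAGAUGCAGAACGCUUUGGUGACGUCGGGGCUGACACCCUGGGUCAUAUCGCAGAAGCUUGUGCCAAAGGCGAAGCUGAUAACGGUCGUAAAGGCCCGCUCAAUCUGCCAAAUCUGACCCGUCUGGGGCUGGCGAAAGCACACGAAGGUUCUACCGGUUUCAUUCC
primer	ACGTGTCATGACTGACACTGGCAGTACGTAGCAGTGGTAGAACCTTCGTGTGC
oligo	TTCTACCACGGAACTGCTACGTACTGCCAGTGTCAGTCATGACACGT
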