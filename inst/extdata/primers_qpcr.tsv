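name	seq_fwd	seq_rev	anneal_C	conc_nM	expected_bp
RPLP0	TGTGGGCTCCAAGCAGATGCA	GCAGCAGTTTCTCCAGAGCTGGG	60.0	200	137
Luc	GTGTTGGGCGCGTTATTTAT	TACGGTAGGCTGCGAAATGT	60.7	200	102
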