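name	seq_fwd	seq_rev	anneal_C	conc_nM	expected_bp
GAPDH	GGGAGGTAGAGGGGTGATGT	TTCAGCTCAGGGATGACCTT	60.0	400	204
Luc	TGAAGAGATACGCCCTGGTT	CCAACACCGGCATAAAGAAT	59.8	400	198
CMV	GCGTGGATAGCGGTTTGACT	CAATGGGGCGGAGTTGTTAC	60.1	400	124
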