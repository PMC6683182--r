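cell_line	chromosomes
C4-2B	83
PC3	62
MDA-MB-231	67
standard	46
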