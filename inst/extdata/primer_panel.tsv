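name	fwd_seq	rev_seq	gene
cox2	CAAAGATGGATTCGACGGTTGG	CCGGTATCAAACTCGCCCTT	cox2
cox3	GGTTCAACGACACCCATTT	TAGCGTGATGAGCCCATG	cox3
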