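species	gene	length_bp	start_codon	stop_codon	direction
Rphilippinarum	COX1	1719	ATA	TAG	+
Rphilippinarum	ND1	930	ATA	TAA	+
Rphilippinarum	ND2	1035	ATT	TAG	+
Rphilippinarum	ND4L	282	ATT	TAA	+
Rphilippinarum	COX2	1995	ATC	TAA	+
Rphilippinarum	COX2	1608	ATA	TAA	+
Rphilippinarum	CYTB	1224	ATT	TAA	+
Rphilippinarum	ATP8	120	ATT	TAG	+
Rphilippinarum	ND4	1359	ATG	TAA	+
Rphilippinarum	ATP6	738	ATA	TAG	+
Rphilippinarum	ND3	405	GTG	TAA	+
Rphilippinarum	ND5	1665	TTG	TAA	+
Rphilippinarum	ND6	510	TTG	TAA	+
Rphilippinarum	COX3	864	ATT	TAA	+
Rvariegatus	COX1	1758	GTG	TAG	+
Rvariegatus	ND1	933	ATG	TAG	+
Rvariegatus	ND2	1029	ATG	TAG	+
Rvariegatus	COX2	1416	TTG	TAG	+
Rvariegatus	CYTB	1239	ATT	TAA	+
Rvariegatus	ATP8	120	TTG	TAA	+
Rvariegatus	ND4	1356	ATG	TAA	+
Rvariegatus	ATP6	735	ATG	TAG	+
Rvariegatus	ND3	405	ATG	TAA	+
Rvariegatus	ND5	1704	GTG	TAA	+
Rvariegatus	ND4L	279	ATG	TAG	+
Rvariegatus	ND6	522	ATG	TAG	+
Rvariegatus	COX3	882	ATT	TAA	+
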