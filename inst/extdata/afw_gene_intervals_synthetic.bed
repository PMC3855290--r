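# Synthetic stand-in gene intervals (BED, 0-based half-open; 5th column flags
# non-coding genes).  Gene symbols are those annotated to the published
# regions; coordinates are constructed inside the printed region bounds.
27	920000	940000	GOSR2	coding
27	980000	1000000	GJC1	coding
27	1050000	1070000	CCDC43	coding
27	1120000	1140000	WNT3	coding
27	1180000	1220000	NSF	coding
27	1250000	1290000	EFTUD2	coding
3	34900000	34950000	PLD5	coding
3	35000000	35050000	PIGM	coding
3	35100000	35100200	MIR1784	noncoding
3	35400000	35500000	RGS7	coding
3	35700000	35900000	CHRM3	coding
14	7150000	7200000	PDPK1	coding
14	7250000	7300000	UBE2I	coding
14	7350000	7400000	IL21R	coding
9	17000000	17100000	MFN1	coding
9	17200000	17300000	PIK3CA	coding
18	10200000	10250000	TIMP2	coding
18	10300000	10350000	SOCS3	coding
18	10400000	10400200	MIR1652	noncoding
18	10900000	10950000	GRB2	coding
18	11000000	11050000	SUMO2	coding
2	50000000	50050000	OFFREGION1	coding
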