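chr7	55086713	55324313	EGFR
chr8	38268655	38326352	FGFR1
chr8	128748314	128753680	MYC
chr10	89623194	89728532	PTEN
chr13	32889610	32973805	BRCA2
chr13	48877886	49056122	RB1
chr17	41196311	41277500	BRCA1
chrX	66764464	66950461	AR
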