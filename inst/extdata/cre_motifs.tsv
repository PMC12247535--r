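element_name	iupac_pattern	category
MBS	CAACTG	stress
LTR	CCGAAA	stress
TC-rich	ATTTTCTTCA	stress
ABRE	TACGTGTC	hormone
P-box	CCTTTTG	hormone
CGTCA-motif	CGTCA	hormone
CAT-box	GCCACT	growth
O2-site	GATGAYRTGR	growth
CCGTCC-box	CCGTCC	growth
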