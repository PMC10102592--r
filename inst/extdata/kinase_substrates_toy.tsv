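GENE	KINASE	SUB_GENE	SUB_MOD_RSD	KIN_ORGANISM	SUB_ORGANISM
AKT1	Akt1	GSK3B	S9	human	human
AKT1	Akt1	MTOR	S2448	human	human
AKT1	Akt1	BAD	S99	human	human
CDK2	CDK2	RB1	S807	human	human
CDK2	CDK2	NPM1	T199	human	human
MAPK3	ERK1	RPS6KA1	T359	human	human
MAPK3	ERK1	ELK1	S383	human	human
MAPK1	ERK2	ELK1	S383	human	human
CSNK2A1	CK2A1	CTNNB1	S552	mouse	mouse
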