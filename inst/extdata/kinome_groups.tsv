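kinase	group
AKT1	AGC
AKT2	AGC
AURKB	AGC
LATS1	AGC
PDPK1	AGC
PRKACA	AGC
PRKCA	AGC
PRKCZ	AGC
KPCZ	AGC
ROCK1	AGC
RPS6KB1	AGC
KS6B1	AGC
SGK1	AGC
STK38	AGC
CAMK2A	CAMK
CHEK1	CAMK
DCLK1	CAMK
MAPKAPK2	CAMK
MARK2	CAMK
PRKAA1	CAMK
CSNK1A1	CK1
CSNK1D	CK1
CSNK1E	CK1
VRK1	CK1
CDK1	CMGC
CDK2	CMGC
CDK4	CMGC
CDK6	CMGC
CLK1	CMGC
DYRK1A	CMGC
GSK3B	CMGC
MAPK1	CMGC
MAPK13	CMGC
MAPK14	CMGC
MAPK3	CMGC
MAPK8	CMGC
MAP2K1	STE
MAP2K2	STE
PAK1	STE
STK3	STE
STK4	STE
ABL1	TK
EGFR	TK
FYN	TK
INSR	TK
JAK2	TK
LCK	TK
SRC	TK
ACVR1	TKL
BRAF	TKL
IRAK1	TKL
RAF1	TKL
RIPK2	TKL
NPR1	RGC
NPR2	RGC
ATM	Atypical
ATR	Atypical
MTOR	Atypical
PDK2	Atypical
PRKDC	Atypical
AURKA	Other
NEK2	Other
PLK1	Other
TTK	Other
WEE1	Other
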