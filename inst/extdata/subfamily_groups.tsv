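subfamily	group
RLK-Pelle_DLSV	RLK
RLK-Pelle_LRR-XI-1	RLK
RLK-Pelle_LRR-XII-1	RLK
RLK-Pelle_LRR-I-1	RLK
RLK-Pelle_CrRLK1L-1	RLK
RLK-Pelle_RLCK-VIIa-2	RLK
RLK-Pelle_RLCK-XI	RLK
RLK-Pelle_LysM	RLK
RLK-Pelle_WAK	RLK
RLK-Pelle_L-LEC	RLK
RLK-Pelle_LRK10L-2	RLK
RLK-Pelle_URK-4	RLK
AGC_NDR	AGC
AGC_RSK-2	AGC
AGC_Pl	AGC
AGC_PDK1	AGC
CAMK_CDPK	CAMK
CAMK_AMPK	CAMK
CAMK_CAMKL-CHK1	CAMK
CAMK_CAMKL-LKB	CAMK
CAMK_OST1L	CAMK
CMGC_MAPK	CMGC
CMGC_GSK	CMGC
CMGC_CDK-CRK7-CDK9	CMGC
CMGC_SRPK	CMGC
CMGC_CDKL-Os	CMGC
STE_STE11	STE
STE_STE20	STE
STE_STE7	STE
TKL-Pl-3	TKL
TKL_IRAK	TKL
TKL_CTR1-DRK-2	TKL
CK1_CK1	other
WNK_NRBP	other
Aur	other
ULK_ULK4	other
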