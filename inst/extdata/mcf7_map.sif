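ER	1	SHC
EGFR	1	SHC
HER2	1	SHC
INSR	1	SHC
EGFR	1	PKC
PKC	1	RAS
SHC	1	RAS
RAS	1	MEK
MEK	1	ERK
RAS	1	JNK
JNK	1	CJUN
ERK	1	CMYC
ERK	1	RB
ERK	-1	BAD
HER2	1	PI3K
INSR	1	PI3K
PI3K	1	AKT
AKT	1	MTOR
AKT	-1	BAD
AKT	-1	PGSK3
AKT	1	NFKB
MTOR	1	P70S6K
AMPK	-1	MTOR
AMPK	1	P53
HSP90	1	HIF1
HSP90	1	AKT
HSP90	1	NFKB
HIF1	1	CMYC
HDAC1	-1	P53
HDAC1	-1	RB
ATM	1	BRCA1
ATM	1	P53
BRCA1	1	P53
P53	1	P21
P53	1	BAD
BRCA1	1	RRM2
P53	-1	PLK1
ERK	1	PLK1
NFKB	1	BCL2
RB	1	CELL_CYCLE
PLK1	1	CELL_CYCLE
P21	1	DNA_REPAIR
RRM2	1	DNA_REPAIR
NFKB	1	CELL_SURVIVAL
BAD	-1	CELL_SURVIVAL
BCL2	1	CELL_SURVIVAL
PGSK3	1	CELL_GROWTH
P70S6K	1	CELL_GROWTH
CMYC	1	CELL_GROWTH
CJUN	1	CELL_GROWTH
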