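id	role	observed	display_name
ER	protein	TRUE	Estrogen receptor
EGFR	protein	FALSE	EGF receptor
HER2	protein	FALSE	HER2/ERBB2
INSR	protein	FALSE	Insulin receptor
SHC	protein	FALSE	SHC adaptor
PKC	protein	TRUE	Protein kinase C
RAS	protein	FALSE	RAS GTPase
MEK	protein	TRUE	MAP2K1/2
ERK	protein	TRUE	ERK1/2
JNK	protein	TRUE	JNK stress kinase
PI3K	protein	FALSE	PI3 kinase
AKT	protein	TRUE	AKT/PKB
MTOR	protein	TRUE	mTOR
AMPK	protein	FALSE	AMP-activated kinase
HSP90	protein	FALSE	Heat-shock protein 90
HIF1	protein	TRUE	HIF1-alpha
HDAC1	protein	FALSE	Histone deacetylase 1
ATM	protein	FALSE	ATM kinase
BRCA1	protein	TRUE	BRCA1
P53	protein	TRUE	p53
RB	transcription_factor	TRUE	Retinoblastoma protein
PLK1	transcription_factor	FALSE	Polo-like kinase 1
P21	transcription_factor	FALSE	p21/CDKN1A
RRM2	transcription_factor	FALSE	Ribonucleotide reductase M2
NFKB	transcription_factor	TRUE	NF-kB
BAD	transcription_factor	TRUE	BAD
BCL2	transcription_factor	FALSE	BCL-2
PGSK3	transcription_factor	TRUE	phospho-GSK3
P70S6K	transcription_factor	TRUE	p70 S6 kinase
CMYC	transcription_factor	FALSE	c-MYC
CJUN	transcription_factor	FALSE	c-JUN
CELL_CYCLE	output	FALSE	Cell cycle regulation
DNA_REPAIR	output	FALSE	DNA repair
CELL_SURVIVAL	output	FALSE	Cell survival
CELL_GROWTH	output	FALSE	Cell growth
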