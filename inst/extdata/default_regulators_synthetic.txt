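# Default regulator list bundled with keyreg.
# SYNTHETIC STAND-IN: a curated-by-construction list of widely studied
# human transcription-factor gene symbols, provided so the pipeline runs
# out of the box. Replace with your own regulator list (one ID per line,
# hash comments allowed) for real analyses.
AHR
ALX1
ALX3
ALX4
AR
ARID3A
ARID5B
ARNT
ARNTL
ATF1
ATF2
ATF3
ATF4
ATF5
ATF6
ATF6B
ATF7
BACH1
BACH2
BARX1
BARX2
BCL11A
BCL11B
BCL6
BHLHE40
BHLHE41
CDX1
CDX2
CEBPA
CEBPB
CEBPD
CEBPE
CEBPG
CLOCK
CREB1
CREB3
CREB5
CRX
CRY1
CRY2
CTCF
CUX1
CUX2
DBP
DLX1
DLX2
DLX3
DLX4
DLX5
DLX6
E2F1
E2F2
E2F3
E2F4
E2F5
E2F6
E2F7
E2F8
EBF1
EBF2
EBF3
EGR1
EGR2
EGR3
EGR4
ELF1
ELF2
ELF3
ELF4
ELF5
ELK1
ELK3
ELK4
EMX1
EMX2
EN1
EN2
EOMES
EPAS1
ERG
ESR1
ESR2
ESRRA
ESRRB
ESRRG
ETS1
ETS2
ETV1
ETV2
ETV3
ETV4
ETV5
ETV6
ETV7
FLI1
FOS
FOSB
FOSL1
FOSL2
FOXA1
FOXA2
FOXA3
FOXM1
FOXO1
FOXO3
FOXO4
FOXO6
FOXP1
FOXP2
FOXP3
FOXP4
GABPA
GATA1
GATA2
GATA3
GATA4
GATA5
GATA6
GLI1
GLI2
GLI3
GRHL1
GRHL2
GRHL3
GSX1
GSX2
HAND1
HAND2
HES1
HES2
HES3
HES4
HES5
HES6
HES7
HEY1
HEY2
HIF1A
HLF
HMX1
HMX2
HMX3
HNF1A
HNF1B
HNF4A
HNF4G
HOXA1
HOXA10
HOXA11
HOXA13
HOXA2
HOXA3
HOXA4
HOXA5
HOXA6
HOXA7
HOXA9
HOXB1
HOXB13
HOXB2
HOXB3
HOXB4
HOXB5
HOXB6
HOXB7
HOXB8
HOXB9
HOXC10
HOXC11
HOXC12
HOXC13
HOXC4
HOXC5
HOXC6
HOXC8
HOXC9
HOXD1
HOXD10
HOXD11
HOXD12
HOXD13
HOXD3
HOXD4
HOXD8
HOXD9
HSF1
HSF2
HSF4
ID1
ID2
ID3
ID4
IKZF1
IKZF2
IKZF3
IRF1
IRF2
IRF3
IRF4
IRF5
IRF6
IRF7
IRF8
IRF9
ISL1
ISL2
JUN
JUNB
JUND
KLF1
KLF10
KLF11
KLF12
KLF13
KLF14
KLF15
KLF16
KLF17
KLF2
KLF3
KLF4
KLF5
KLF6
KLF7
KLF8
KLF9
LEF1
LHX1
LHX2
LHX3
LHX4
LHX5
LHX6
MAF
MAFA
MAFB
MAFF
MAFG
MAFK
MEF2A
MEF2B
MEF2C
MEF2D
MEIS1
MEIS2
MEIS3
MITF
MLX
MLXIP
MLXIPL
MNX1
MSX1
MSX2
MTF1
MXD1
MXD3
MXD4
MYB
MYBL1
MYBL2
MYC
MYCL
MYCN
NANOG
NEUROD1
NEUROD2
NEUROD4
NEUROD6
NEUROG1
NEUROG2
NEUROG3
NFAT5
NFATC1
NFATC2
NFATC3
NFATC4
NFE2L2
NFIL3
NFKB1
NFKB2
NFYA
NFYB
NFYC
NKX2-1
NKX2-2
NKX2-3
NKX2-5
NKX2-8
NPAS2
NR1D1
NR1D2
NR1H2
NR1H3
NR1H4
NR3C1
NR3C2
NR4A1
NR4A2
NR4A3
NR5A1
NR5A2
NRF1
OLIG1
OLIG2
OLIG3
ONECUT1
ONECUT2
OSR1
OSR2
OTX1
OTX2
PAX1
PAX2
PAX3
PAX4
PAX5
PAX6
PAX7
PAX8
PAX9
PBX1
PBX2
PBX3
PDX1
PER1
PER2
PHOX2A
PHOX2B
PITX1
PITX2
PITX3
PKNOX1
POU2F1
POU2F2
POU2F3
POU5F1
PPARA
PPARD
PPARG
PRDM1
PRDM16
PRRX1
PRRX2
PTF1A
RARA
RARB
RARG
RAX
REL
RELA
RELB
RORA
RORB
RORC
RUNX1
RUNX2
RUNX3
RXRA
RXRB
RXRG
SATB1
SATB2
SHOX2
SIX1
SIX2
SIX3
SIX4
SIX5
SIX6
SMAD1
SMAD2
SMAD3
SMAD4
SMAD5
SMAD6
SMAD7
SMAD8
SMAD9
SNAI1
SNAI2
SNAI3
SOX1
SOX10
SOX11
SOX12
SOX13
SOX14
SOX15
SOX17
SOX18
SOX2
SOX21
SOX3
SOX30
SOX4
SOX5
SOX6
SOX7
SOX8
SOX9
SP1
SP100
SP110
SP140
SP2
SP3
SP4
SP5
SP6
SP7
SP8
SP9
SPI1
SPIB
SREBF1
SREBF2
SRF
STAT1
STAT2
STAT3
STAT4
STAT5A
STAT5B
STAT6
TBP
TBPL1
TBR1
TBX1
TBX10
TBX15
TBX18
TBX19
TBX2
TBX20
TBX21
TBX22
TBX3
TBX4
TBX5
TBX6
TCF12
TCF15
TCF19
TCF21
TCF3
TCF4
TCF7
TCF7L1
TCF7L2
TEAD1
TEAD2
TEAD3
TEAD4
TEF
TFAP2A
TFAP2B
TFAP2C
TFAP4
TFCP2
TFCP2L1
TFE3
TFEB
TFEC
THRA
THRB
TP53
TP63
TP73
TWIST1
TWIST2
USF1
USF2
VAX1
VAX2
VDR
VSX1
VSX2
XBP1
YY1
YY2
ZBTB16
ZBTB20
ZBTB7A
ZEB1
ZEB2
ZIC1
ZIC2
ZIC3
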