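ALX1
ANKHD1-EIF4EBP3
ARHGAP15
ATXN7
AVPR1A
BACH2
C6orf174
CD24
CD247
CLDN11
CLVS2
CSDAP1
DLX6AS
DNASE1L2
ERBB4
ESRP2
FAM171A2
FAM179A
FBN2
FBXO39
FOXG1
GABRB2
GALNT13
GJB6
GLIPR1L2
GNAS
GNMT
GRIK2
HERC2
HOXC11
HOXD1
HOXD11
HOXD8
HPSE2
KHDRBS2
KSR2
LHX8
LRP5
MAPK8IP3
MIR2277
MSX2
NKAIN3
NKX6-2
PAX7
PCDH10
PEG10
PF4
PHYHIPL
PITX2
POU4F2
PPP2R5E
PRH1
PTPN13
RBM33
RPLP1
RSPO2
SFRP2
SGCE
SHROOM1
SLC6A11
SOX11
SPATA18
SPTBN1
TRIM2
TWIST1
UPB1
WDR60
WDR8
WNT6
WT1
WWP2
ZBTB16
ZNF471
ZNF577
ZNF714
ZNF83
ZSCAN1
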