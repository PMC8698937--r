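HOMEOBOX	homeodomain transcription factors	ALX1	HOXC11	HOXD1	HOXD8	HOXD11	LHX8	MSX2	NKX6-2	PAX7	POU4F2	FOXG1	PITX2	TWIST1	WT1	DLX6AS
ZINC_FINGER	zinc finger transcription factors	ZBTB16	ZNF83	ZNF471	ZNF577	ZNF714	ZSCAN1
WNT_SIGNALING	wnt pathway members	WNT6	SFRP2	RSPO2	LRP5
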