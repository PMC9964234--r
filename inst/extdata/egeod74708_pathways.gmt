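Signal transduction	E-GEOD-74708 in-flight vs pre-flight DEG pathway set	ARHGAP9	CCL2	CCNC	CHN1	CLTB	COL4A4	CREB1	CRHR1	CTNNBIP1	HIF1A	KIDINS220	NFATC1	PDPK1	SOS2	THBS3	YES1
Immune system	E-GEOD-74708 in-flight vs pre-flight DEG pathway set	ATF2	BIRC2	CREB1	EIF4E2	IL7	NFATC1	PDPK1	UBA5	UBR4	XAF1	YES1
Gene expression	E-GEOD-74708 in-flight vs pre-flight DEG pathway set	AARS2	CCNC	RRN3	ZNF184	ZNF253	ZNF529	ZNF606	ZNF664	ZNF699	ZNF711
Metabolism	E-GEOD-74708 in-flight vs pre-flight DEG pathway set	ACSL4	ARSK	CCNC	GM2A	GPT	HACL1	NDUFA1	PIKFYVE	PSAT1
Metabolism of proteins	E-GEOD-74708 in-flight vs pre-flight DEG pathway set	ARSK	CCL2	DPP4	GNE	MAGT1	PCSK1	SPON2	XRN2
Generic transcription pathway	E-GEOD-74708 in-flight vs pre-flight DEG pathway set	CCNC	ZNF184	ZNF253	ZNF529	ZNF606	ZNF664	ZNF699	ZNF711
Developmental biology	E-GEOD-74708 in-flight vs pre-flight DEG pathway set	CCNC	CLTB	COL4A4	CREB1	SCN2B	SOS2	YES1
Metabolism of lipids and lipoproteins	E-GEOD-74708 in-flight vs pre-flight DEG pathway set	ACSL4	ARSK	CCNC	GM2A	HACL1	PIKFYVE
Axon guidance	E-GEOD-74708 in-flight vs pre-flight DEG pathway set	CLTB	COL4A4	CREB1	SCN2B	SOS2	YES1
Innate immune system	E-GEOD-74708 in-flight vs pre-flight DEG pathway set	ATF2	BIRC2	CREB1	NFATC1	PDPK1	YES1
Disease	E-GEOD-74708 in-flight vs pre-flight DEG pathway set	CCNC	CHMP4C	CREB1	CTNNBIP1	HIF1A	PDPK1
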