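IMPRINTED_SYNTHETIC	synthetic stand-in list of well-known imprinted genes; not the published catalogue	H19	IGF2	IGF2R	MEG3	MEG8	DLK1	SNRPN	NDN	MKRN3	MAGEL2	UBE3A	KCNQ1	KCNQ1OT1	CDKN1C	PHLDA2	SLC22A18	PLAGL1	PEG3	PEG10	MEST	GRB10	GNAS	NNAT	RTL1	ZIM2	OSBPL5	ATP10A	DGCR6	SGCE	PPP1R9A
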