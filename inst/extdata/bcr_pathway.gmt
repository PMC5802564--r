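BCR_PATHWAY	B-cell receptor signaling members (synthetic stand-in catalogue)	CD19	EBF1	PAX5	BTK	BLNK	CD79A	CD79B	SYK	LYN	BLK	PLCG2	PIK3CD	NFKB1	CARD11	PRKCB
TCR_PATHWAY	T-cell receptor signaling decoy set	LCK	ZAP70	CD3D	CD3E	CD3G	LAT	ITK	FYN
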