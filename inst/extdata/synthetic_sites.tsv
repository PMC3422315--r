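amplicon_id	gene	site_label	genomic_position	offset	aa_change
HTR2C_syn	HTR2C	A	113988938	30	I/V
HTR2C_syn	HTR2C	B	113988940	32	I/M
HTR2C_syn	HTR2C	E	113988944	36	N/D
HTR2C_syn	HTR2C	C	113988945	37	N/S
HTR2C_syn	HTR2C	D	113988950	42	I/V
GRIA2_syn	GRIA2	Q/Q	1000056	56	Q/Q
GRIA2_syn	GRIA2	Q/R	1000061	61	Q/R
AZIN1_syn	AZIN1	S/G	1000045	45	S/G
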