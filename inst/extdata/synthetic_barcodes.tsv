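sample_id	barcode	group	region	ph	age	pmi
s1	CAGCTA	control	cortex	6.61	48	20.5
s2	TGACTG	control	cerebellum	6.45	37	50
s3	ACGTGA	MDD	cortex	6.02	52	18
s4	GTCAGT	MDD	cerebellum	6.7	61	24
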