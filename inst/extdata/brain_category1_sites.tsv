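# 36 coding-region A-to-I editing sites with mean editing frequency above 1%
# ("Category I") measured by targeted amplicon deep sequencing in three sets
# of normal human brain samples. mean_percent/sem_percent: percent of
# transcripts edited (mean +/- SEM across samples); reads_mean: mean read
# depth at the site; genomic positions on hg18; is_new: 1 = site first
# confirmed in this assay, 0 = previously documented.
gene	site_label	genomic_position	mean_percent	sem_percent	reads_mean	is_new
AZIN1	S/G	chr8:103910812	6.96	0.88	71192	1
BLCAP	Y/C	chr20:35580986	36.84	1.76	13040	0
BLCAP	Q/K	chr20:35580977	37.22	2.43	13040	0
BLCAP	K/R	chr20:35580947	12.96	0.68	13040	0
CCNI	R/G	chr4:78198704	19.73	1.71	92647	1
CCNI	K/R	chr4:78196188	4.25	0.40	99327	1
CRB2	T/A	chr9:125172441	2.63	0.24	36336	1
CYFIP2	K/E	chr5:156669386	69.83	4.38	72192	0
CYFIP2	K/R	chr5:156669387	1.24	0.08	72192	1
FLNA	Q/R	chrX:153233144	18.83	2.09	59725	0
FLNB	Q/R	chr3:58116841	5.48	1.44	58461	1
GABRA3	I/M	chrX:151108975	74.08	3.20	65175	0
GLI1	R/G	chr12:56150891	64.89	3.14	51897	1
GRIA2	Q/Q	chr4:158477325	99.09	0.43	81668	0
GRIA2	Q/R	chr4:158477329	17.83	0.98	81668	0
GRIA2	R/G	chr4:158500744	58.91	4.75	24308	0
GRIA3	R/G	chrX:122426643	91.59	3.00	35143	0
GRIA4	R/G	chr11:105309904	3.65	0.38	13651	0
GRIK1	Q/R	chr21:29875621	56.92	2.67	72065	0
GRIK2	I/V	chr6:102444382	55.78	2.92	52960	0
GRIK2	Y/C	chr6:102444395	81.79	3.52	52960	0
GRIK2	Q/R	chr6:102479281	77.26	2.89	42994	0
HTR2C	A (I/V)	chrX:113988938	68.02	4.11	63901	0
HTR2C	B (I/M)	chrX:113988940	41.78	4.15	63901	0
HTR2C	E (N/D)	chrX:113988944	15.12	1.60	63901	0
HTR2C	C (N/S)	chrX:113988945	45.87	3.16	63901	0
HTR2C	D (I/V)	chrX:113988950	56.21	2.63	63901	0
IGFBP7	R/G	chr4:57671043	14.90	2.52	1236	0
IGFBP7	K/R	chr4:57670991	49.76	1.93	29167	0
KCNA1	I/V	chr12:4892003	14.59	1.38	62447	0
KCNMA1	S/G	chr10:79067304	20.66	1.57	43534	1
NCSTN	S/G	chr1:158586611	9.08	0.90	75689	1
NEIL1	K/R	chr15:73433139	98.80	0.25	7651	0
NEIL1	K/K	chr15:73433140	92.12	0.88	7651	0
TRO	S/G	chrX:54972292	9.55	0.95	52312	1
TTLL3	K/R	chr3:9851560	4.17	0.39	54057	1
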