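Protein IDs	Gene names	Unique peptides	Reverse	Only identified by site	LFQ intensity S1_r1	LFQ intensity S1_r2	LFQ intensity S1_r3	LFQ intensity S2_r1	LFQ intensity S2_r2	LFQ intensity S2_r3	LFQ intensity S3_r1	LFQ intensity S3_r2	LFQ intensity S3_r3	LFQ intensity S4_r1	LFQ intensity S4_r2	LFQ intensity S4_r3
P_ALL	ALL	5			32	32	32	32	32	32	32	32	32	32	32	32
P_MED	MED	4			4	8	0	8	8	8	2	2	2	16	16	0
P_HALF	HALF	3			64	64	64	16	16	16	0	0	0	0	0	0
P_RUNBOUND	RUNB	3			128	128	128	0	0	0	0	0	0	0	0	0
P_REV	REV	6	+		50	50	50	50	50	50	50	50	50	50	50	50
P_SITE	SITE	4		+	50	50	50	50	50	50	50	50	50	50	50	50
P_1PEP	PEP1	1			50	50	50	50	50	50	50	50	50	50	50	50
P_RARE	RARE	3			40	40	0	0	0	0	0	0	0	0	0	0
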