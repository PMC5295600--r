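marker_a	marker_b	lg_a	lg_b	parental_1	parental_1_count	parental_2	parental_2_count	recomb_1	recomb_1_count	recomb_2	recomb_2_count
TP47181	TP21253	AC13	pseudolink	G/A	32	C/G	25	C/A	23	G/G	5
TP21253	TP30908	pseudolink	AC34	A/T	43	G/C	23	A/C	12	G/T	7
TP47181	TP30908	AC13	AC34	G/T	23	C/C	21	C/T	27	G/C	14
TP10591	TP15996	AC21	pseudolink	T/G	14	G/A	13	G/G	4	T/A	1
TP15996	TP32826	pseudolink	AC01	G/A	18	A/T	14	A/A	0	G/T	0
TP10591	TP32826	AC21	AC01	T/A	22	G/T	27	G/A	23	T/T	10
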