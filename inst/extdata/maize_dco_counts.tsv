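chromosome	region	n2s	n3s	n4s	ci_printed
chr1	whole	23	57	30	0.06
chr1	same_arm	18	47	21	0.04
chr1	spans_centromere	5	10	9	0.17
chr2	whole	17	47	19	0.02
chr2	same_arm	10	31	18	0.14
chr2	spans_centromere	7	16	1	-0.25
chr3	whole	15	52	11	-0.05
chr3	same_arm	8	36	10	0.04
chr3	spans_centromere	7	16	1	-0.25
chr4	whole	15	39	17	0.03
chr4	same_arm	6	29	13	0.15
chr4	spans_centromere	9	10	4	-0.22
chr5	whole	18	44	15	-0.04
chr5	same_arm	12	34	7	-0.09
chr5	spans_centromere	6	10	8	0.08
chr6	whole	23	25	16	-0.11
chr6	same_arm	21	21	11	-0.19
chr6	spans_centromere	2	4	5	0.27
chr7	whole	14	25	17	0.05
chr7	same_arm	8	13	11	0.09
chr7	spans_centromere	6	12	6	0
chr8	whole	11	34	16	0.08
chr8	same_arm	8	19	10	0.05
chr8	spans_centromere	3	15	6	0.13
chr9	whole	12	21	10	-0.05
chr9	same_arm	5	11	4	-0.05
chr9	spans_centromere	7	10	6	-0.04
chr10	whole	12	22	7	-0.12
chr10	same_arm	6	8	4	-0.11
chr10	spans_centromere	6	14	3	-0.13
total	whole	160	366	158	-0.003
total	same_arm	102	249	109	0.02
total	spans_centromere	58	117	49	-0.04
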