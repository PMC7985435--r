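chromosome	region	n2s	n3s	n4s	ci_printed
chr1	whole	33	44	24	-0.09
chr1	same_arm	18	20	11	-0.14
chr1	spans_centromere	15	24	13	-0.04
chr2	whole	24	52	22	-0.02
chr2	same_arm	12	23	18	0.11
chr2	spans_centromere	12	29	4	-0.18
chr3	whole	20	33	13	-0.11
chr3	same_arm	9	9	5	-0.17
chr3	spans_centromere	11	24	8	-0.07
chr4	whole	20	28	21	0.01
chr4	same_arm	12	9	9	-0.10
chr4	spans_centromere	8	19	12	0.10
chr5	whole	15	21	15	0
chr5	same_arm	4	5	5	0.07
chr5	spans_centromere	11	16	10	-0.03
total	whole	112	178	95	-0.04
total	same_arm	55	66	48	-0.04
total	spans_centromere	57	112	47	-0.05
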