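pathology	microbiology	micro_concordant	certainty
0	0	NA	no_diagnosis
0	1	NA	no_diagnosis
0	2	NA	no_diagnosis
0	3	NA	low
0	4	NA	moderate
1	0	NA	low
1	1	N	low
1	1	Y	low
1	2	N	low
1	2	Y	low
1	3	N	moderate
1	3	Y	moderate
1	4	N	moderate
1	4	Y	moderate
2	0	NA	low
2	1	N	low
2	1	Y	low
2	2	N	low
2	2	Y	moderate
2	3	N	moderate
2	3	Y	moderate
2	4	N	moderate
2	4	Y	high
3	0	NA	moderate
3	1	N	moderate
3	1	Y	moderate
3	2	N	moderate
3	2	Y	high
3	3	N	high
3	3	Y	high
3	4	N	high
3	4	Y	very_high
4	0	NA	high
4	1	N	high
4	1	Y	high
4	2	N	high
4	2	Y	high
4	3	N	high
4	3	Y	very_high
4	4	N	very_high
4	4	Y	very_high
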