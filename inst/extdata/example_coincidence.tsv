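category	n	perfect_or_almost	moderate	low	none
overall	48	32	4	3	9
infectious_diseases	39	24	3	3	9
malignant_tumors	7	7	0	0	0
other_diseases	2	1	1	0	0
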