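mia	infectious_diseases	malignant_tumors	congenital_malformations	other_diseases	nonconclusive
infectious_diseases	39	0	2	1	0
malignant_tumors	0	7	0	0	0
congenital_malformations	0	0	0	0	0
other_diseases	1	0	0	2	0
nonconclusive	2	0	0	0	0
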