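case_id,age_months,sex,mia_code,mia_chain,mia_underlying,mia_other,mia_path_level,mia_micro_level,mia_micro_concordant,mia_histo_org_inflam,mia_certainty,cda_code,cda_chain,cda_underlying,cda_other,cda_path_level,cda_micro_level,cda_micro_concordant,cda_histo_org_inflam,cda_certainty
case01,36,F,A41.5,A41.5;J15.9,B20,,4,4,Y,FALSE,very_high,A41.5,,B20,,4,4,Y,FALSE,very_high
case02,150,F,A41.5,,B20,,4,4,Y,FALSE,very_high,A41.5,,B20,,4,4,Y,FALSE,very_high
case03,3,M,A41.9,,E43,,4,4,Y,FALSE,very_high,A41.9,,E43,,4,4,Y,FALSE,very_high
case04,72,M,A40.8,,,,4,4,Y,FALSE,very_high,A40.8,,,,4,4,Y,FALSE,very_high
case05,2,M,J15.9,,,,4,4,Y,FALSE,very_high,J15.9,,,,4,4,Y,FALSE,very_high
case06,150,M,J15.5,,,,4,4,Y,FALSE,very_high,J15.5,,,,4,4,Y,FALSE,very_high
case07,60,F,J18.9,,,,4,4,Y,FALSE,very_high,J18.9,,,,4,4,Y,FALSE,very_high
case08,168,F,J13,,,,4,4,Y,FALSE,very_high,J13,,,,4,4,Y,FALSE,very_high
case09,2,M,B50.8,,B20,,4,4,Y,FALSE,very_high,B50.8,,B20,,4,4,Y,FALSE,very_high
case10,8,F,B50.0,,E43,,4,4,Y,FALSE,very_high,B50.0,,E43,,4,4,Y,FALSE,very_high
case11,8,M,A19.9,,,,4,4,Y,FALSE,very_high,A19.9,,,,4,4,Y,FALSE,very_high
case12,2,M,A19.0,,,,4,4,Y,FALSE,very_high,A19.0,,,,4,4,Y,FALSE,very_high
case13,180,M,G00.1,,,,4,4,Y,FALSE,very_high,G00.1,,,,4,4,Y,FALSE,very_high
case14,180,M,G04.9,,,,3,3,N,FALSE,high,G04.9,,,,4,4,Y,FALSE,very_high
case15,4,M,A87.9,,E43,,3,3,N,FALSE,high,A87.9,,E43,,4,4,Y,FALSE,very_high
case16,16,M,K65.0,,,,3,3,N,FALSE,high,K65.0,,,,3,3,N,FALSE,high
case17,4,M,N10,,,,3,3,N,FALSE,high,N10,,,,3,3,N,FALSE,high
case18,180,M,A02.1,,,,3,3,N,FALSE,high,A02.1,,,,3,3,N,FALSE,high
case19,180,F,A41.5,,,,3,3,N,FALSE,high,A41.8,,,,3,3,N,FALSE,high
case20,120,F,J15.5,,,,3,3,N,FALSE,high,J15.9,,,,3,3,N,FALSE,high
case21,2,F,B50.0,,,,3,3,N,FALSE,high,B50.8,,,,3,3,N,FALSE,high
case22,96,M,A19.0,,,,3,3,N,FALSE,high,A19.9,,,,3,3,N,FALSE,high
case23,16,M,G00.2,,,,3,3,N,FALSE,high,G00.8,,,,3,3,N,FALSE,high
case24,30,M,A87.0,,B20,,3,3,N,FALSE,high,A87.8,,B20,,3,3,N,FALSE,high
case25,18,M,A40.1,,,,3,3,N,FALSE,high,A41.5,,,,3,3,N,FALSE,high
case26,168,F,J12.8,,,,3,3,N,FALSE,high,J15.9,,,,3,3,N,FALSE,high
case27,9,M,G00.9,,,,3,3,N,FALSE,high,G04.9,,,,3,3,N,FALSE,high
case28,150,F,A41.5,,,,2,2,Y,FALSE,moderate,B50.8,,,,3,3,N,FALSE,high
case29,36,M,A87.9,,,,2,2,Y,FALSE,moderate,A41.5,,,,3,3,N,FALSE,high
case30,17,M,J15.9,,,,2,2,Y,FALSE,moderate,J22,,,,3,3,N,FALSE,high
case31,168,M,J15.9,,,,2,2,Y,FALSE,moderate,A41.5,,,,3,3,N,FALSE,high
case32,15,M,J18.9,,,,2,2,Y,FALSE,moderate,A40.8,,,,3,3,N,FALSE,high
case33,30,F,J15.0,C83.7;N17.9,B20,,2,2,Y,FALSE,moderate,A41.9,,B20,,3,3,N,FALSE,high
case34,48,F,J15.9,,B20,,2,2,Y,FALSE,moderate,A85.0,,B20,,2,3,N,TRUE,high
case35,6,M,A41.5,,,,2,2,Y,FALSE,moderate,J18.9,,,,2,2,Y,FALSE,moderate
case36,4,M,J15.9,,,,2,2,Y,FALSE,moderate,K65.9,,,,2,2,Y,FALSE,moderate
case37,24,M,J18.9,,,,2,2,Y,FALSE,moderate,K65.0,,,,2,2,Y,FALSE,moderate
case38,12,M,A40.9,,,,1,1,N,FALSE,low,K65.9,,,,2,2,Y,FALSE,moderate
case39,24,M,J15.9,,,,1,1,N,FALSE,low,N12,,,,2,2,Y,FALSE,moderate
case40,7,F,C83.7,,,,4,4,Y,FALSE,very_high,C83.7,,,,4,4,Y,FALSE,very_high
case41,9,M,C83.7,,,,4,4,Y,FALSE,very_high,C83.7,,,,4,4,Y,FALSE,very_high
case42,5,F,C83.7,,,,4,4,Y,FALSE,very_high,C83.7,,,,4,4,Y,FALSE,very_high
case43,2,F,C41.9,,,,4,4,Y,FALSE,very_high,C41.9,,,,4,4,Y,FALSE,very_high
case44,180,M,C71.9,,,,4,4,Y,FALSE,very_high,C71.9,,,,4,4,Y,FALSE,very_high
case45,14,M,C83.7,,,,4,4,Y,FALSE,very_high,C83.9,,,,4,4,Y,FALSE,very_high
case46,8,M,C41.0,,,,4,4,Y,FALSE,very_high,C41.9,,,,4,4,Y,FALSE,very_high
case47,72,M,I50.0,,,,3,3,N,FALSE,high,I50.0,,,,4,4,Y,FALSE,very_high
case48,36,M,I60.9,,,,2,2,Y,FALSE,moderate,I61.9,,,,2,2,Y,FALSE,moderate
case49,2,F,A41.9,,,,3,3,N,FALSE,high,Q24.8,,,,4,4,Y,FALSE,very_high
case50,180,M,J15.9,,,,3,3,N,FALSE,high,Q04.9,,,,3,3,N,FALSE,high
case51,18,F,J15.9,,,,1,1,N,FALSE,low,J84.1,,,,2,2,Y,FALSE,moderate
case52,7,M,I50.9,,,,1,1,N,FALSE,low,A41.9,,,,1,1,N,FALSE,low
case53,168,M,NONCONCLUSIVE,,,,0,0,,FALSE,no_diagnosis,A41.5,,,,1,1,N,FALSE,low
case54,18,M,NONCONCLUSIVE,,,,0,0,,FALSE,no_diagnosis,B50.8,,,,1,1,N,FALSE,low
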