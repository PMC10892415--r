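region,year,atc_class,did
TOTAL,2018,A10AB,2.8
TOTAL,2018,A10AC,1.8
TOTAL,2018,A10AD,4.0
TOTAL,2018,A10AE,7.0
TOTAL,2018,A10A,15.5
TOTAL,2018,A10BA,24.2
TOTAL,2018,A10BB,14.5
TOTAL,2018,A10BD,22.4
TOTAL,2018,A10BF,0.7
TOTAL,2018,A10BG,0.4
TOTAL,2018,A10BH,7.0
TOTAL,2018,A10BJ,1.6
TOTAL,2018,A10BK,4.4
TOTAL,2018,A10BX,0.2
TOTAL,2018,A10B,75.4
TOTAL,2018,A10,91.0
TOTAL,2021,A10AB,3.3
TOTAL,2021,A10AC,1.3
TOTAL,2021,A10AD,3.3
TOTAL,2021,A10AE,8.1
TOTAL,2021,A10A,16.0
TOTAL,2021,A10BA,24.5
TOTAL,2021,A10BB,11.5
TOTAL,2021,A10BD,28.3
TOTAL,2021,A10BF,0.4
TOTAL,2021,A10BG,0.4
TOTAL,2021,A10BH,7.6
TOTAL,2021,A10BJ,4.9
TOTAL,2021,A10BK,11.2
TOTAL,2021,A10BX,0.1
TOTAL,2021,A10B,88.9
TOTAL,2021,A10,104.9
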