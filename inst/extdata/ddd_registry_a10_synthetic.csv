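atc,ddd_quantity,ddd_unit,route
A10AB01,40,IU,parenteral
A10AC01,40,IU,parenteral
A10AD01,40,IU,parenteral
A10AE04,40,IU,parenteral
A10BA02,2000,mg,oral
A10BB01,10,mg,oral
A10BB09,60,mg,oral
A10BD07,2,UD,oral
A10BF01,300,mg,oral
A10BG03,30,mg,oral
A10BH01,100,mg,oral
A10BJ02,1.2,mg,oral
A10BK01,10,mg,oral
A10BX02,4,mg,oral
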