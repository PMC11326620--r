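country,km2
country_01,1001450
country_02,783562
country_03,551695
country_04,301340
country_05,505990
country_06,131957
country_07,446550
country_08,163610
country_09,2381741
country_10,10400
country_11,20770
country_12,89342
country_13,185180
country_14,1759540
country_15,27400
country_16,110879
country_17,56594
country_18,13812
country_19,25713
country_20,316
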