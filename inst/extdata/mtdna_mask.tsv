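start	end	label
303	317	HVS-II_poly-C
514	523	CA_repeat
568	573	C-stretch_1
956	965	12S_rRNA
3107	3107	historical_3107
5895	5899	C-stretch_2
8272	8289	9bp_indel
16180	16195	HVS-I_poly-C
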