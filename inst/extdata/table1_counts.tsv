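sample	raw_reads	cleaned_reads	unigenes
A_elongata	195890	138867	14210
Collozoum_sp	214475	121079	42784
S_streptacantha	220239	120924	25590
A_scolymantha	195070	126494	42251
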