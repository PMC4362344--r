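subject	taxon
rrna_18S_acantharea	Acantharea
rrna_28S_acantharea	Acantharea
rrna_18S_haptophyta	Haptophyta
rrna_18S_ciliophora	Ciliophora
rrna_18S_polycystinea	Polycystinea
rrna_16S_gammaproteo	Gammaproteobacteria
rrna_16S_alphaproteo	Alphaproteobacteria
rrna_16S_bacteroidetes	Bacteroidetes
rrna_23S_gammaproteo	Gammaproteobacteria
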