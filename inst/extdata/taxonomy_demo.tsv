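# node	parent	rank
root	root	root
Bacteria	root	superkingdom
Proteobacteria	Bacteria	phylum
Alphaproteobacteria	Proteobacteria	class
Betaproteobacteria	Proteobacteria	class
Gammaproteobacteria	Proteobacteria	class
Deltaproteobacteria	Proteobacteria	class
Bacteroidetes	Bacteria	phylum
Planctomycetes	Bacteria	phylum
Cyanobacteria	Bacteria	phylum
Firmicutes	Bacteria	phylum
Actinobacteria	Bacteria	phylum
Eukaryota	root	superkingdom
Rhizaria	Eukaryota	supergroup
Radiolaria	Rhizaria	phylum
Acantharea	Radiolaria	class
Polycystinea	Radiolaria	class
Cercozoa	Rhizaria	phylum
Foraminifera	Rhizaria	phylum
Alveolata	Eukaryota	supergroup
Apicomplexa	Alveolata	phylum
Dinophyceae	Alveolata	class
Ciliophora	Alveolata	phylum
Stramenopiles	Eukaryota	supergroup
Pelagophyceae	Stramenopiles	class
Bacillariophyta	Stramenopiles	class
Haptophyta	Eukaryota	phylum
Opisthokonta	Eukaryota	supergroup
Metazoa	Opisthokonta	kingdom
Fungi	Opisthokonta	kingdom
Choanoflagellata	Opisthokonta	class
Archaeplastida	Eukaryota	supergroup
Chlorophyta	Archaeplastida	phylum
Streptophyta	Archaeplastida	phylum
Amoebozoa	Eukaryota	supergroup
Excavata	Eukaryota	supergroup
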