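go_id	term_name
GO:0005622	intracellular
GO:0005737	cytoplasm
GO:0005739	mitochondrion
GO:0005768	endosome
GO:0005811	lipid particle
GO:0005874	microtubule
GO:0005578	proteinaceous extracellular matrix
GO:0005576	extracellular region
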