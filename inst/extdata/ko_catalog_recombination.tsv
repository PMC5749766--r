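# recBCD / homologous-recombination and replication-restart catalog.
# K03581-K03583 and K01144 are the recBCD-operon orthologs; the
# DNA-polymerase-III and primosome symbols follow KEGG replication gene
# naming (ids for symbols without a printed source are taken from KEGG).
ko_id	symbol	family
K03581	recB	recBCD
K03582	recC	recBCD
K03583	recD	recBCD
K01144	recD2	recBCD
K14162	DPO3A2	dna_pol_III
K03469	rnhA-dnaQ	dna_pol_III
K02343	DPO3T	dna_pol_III
K02339	DPO3C	dna_pol_III
K02340	DPO3P	dna_pol_III
K02342	DPO3E	dna_pol_III
K04067	priB	primosome
K04068	priC	primosome
K04069	dnaT	primosome
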