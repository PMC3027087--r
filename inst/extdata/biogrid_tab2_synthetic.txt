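#BioGRID Interaction ID	Entrez Gene Interactor A	Entrez Gene Interactor B	BioGRID ID Interactor A	BioGRID ID Interactor B	Systematic Name Interactor A	Systematic Name Interactor B	Official Symbol Interactor A	Official Symbol Interactor B	Synonyms Interactor A	Synonyms Interactor B	Experimental System	Experimental System Type	Author	Pubmed ID	Organism Interactor A	Organism Interactor B	Throughput	Score	Modification	Phenotypes	Qualifications	Tags	Source Database
1	5594	5604	111	112	-	-	MAPK1	MAP2K1	ERK2	MEK1	Two-hybrid	physical	Synthetic (2026)	1000001	9606	9606	Low Throughput	-	-	-	-	-	SYNTHETIC
2	1956	2064	113	114	-	-	EGFR	ERBB2	HER1	HER2	Affinity Capture-MS	physical	Synthetic (2026)	1000002	9606	9606	High Throughput	-	-	-	-	-	SYNTHETIC
3	7157	4193	115	116	-	-	TP53	MDM2	p53	-	Reconstituted Complex	physical	Synthetic (2026)	1000003	9606	9606	Low Throughput	-	-	-	-	-	SYNTHETIC
4	6714	2885	117	118	-	-	SRC	GRB2	-	-	Two-hybrid	physical	Synthetic (2026)	1000004	9606	9606	Low Throughput	-	-	-	-	-	SYNTHETIC
5	4087	4089	119	120	-	-	SMAD2	SMAD4	-	-	Affinity Capture-Western	physical	Synthetic (2026)	1000005	9606	9606	Low Throughput	-	-	-	-	-	SYNTHETIC
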