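# Annotated D. melanogaster smORFs with proteomic evidence of translation,
# used as a positive-control validation set for the pipeline filters.
# Columns: gene symbol; length in codons; translated-search E-value against
# D. pseudoobscura (NA = no hit); Ka/Ks (NA = not computable); syntenic
# position conserved in D. pseudoobscura; embryonic RNA-seq contig overlaps.
gene	codons	evalue	kaks	syntenic	overlaps
Akh	79	2e-22	0.04	FALSE	12
CG13551	87	6e-14	0.18	FALSE	12
CG14235	96	5e-42	0.06	TRUE	12
CG17127	98	4e-42	0.05	TRUE	10
CG30415	82	4e-36	0.05	FALSE	12
CG32039	82	1e-15	0.06	FALSE	12
CG3321	81	6e-23	0.05	TRUE	12
Cype	77	8e-26	0.18	TRUE	12
Dbi	86	7e-39	0.48	TRUE	4
Dro	64	4e-17	0.32	TRUE	9
Drs	70	NA	NA	NA	9
IM1	45	1e-12	0.09	TRUE	9
IM2	45	9e-14	0.00	TRUE	9
IM4	42	0.075	0.11	FALSE	12
l(2)06225	99	3e-45	0.00	TRUE	10
Mtk	52	7e-11	0.27	TRUE	12
Nplp2	86	8.4	0.07	FALSE	11
Nplp3	90	1e-10	0.14	FALSE	7
Nplp4	64	NA	NA	NA	12
RpL38	70	8e-34	0.00	FALSE	8
RpS21	83	8e-36	0.02	TRUE	12
RpS27	84	2e-44	0.00	FALSE	12
RpS28b	65	6e-23	0.00	TRUE	12
smt3	90	2e-47	0.00	FALSE	12
sun	61	1e-16	0.16	TRUE	12
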