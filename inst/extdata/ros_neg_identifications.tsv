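protein_name	accession	mw_kda	pi	peptides	mascot_score
A-Kinase anchor protein 4 isoform 2	21493039	94	6.7	34 (54%)	11284
lactotransferrin precursor	54607120	80	8.5	32 (56%)	6049
glyceraldehyde-3-phosphate dehydrogenase, spermatogenic	7657116	44	8.4	12 (48%)	5959
spermatogenic tubulin, beta, 2 precursor	5174735	50	4.7	25 (68%)	5842
semenogelin I isoform a preproprotein	4506883	52	9.3	11 (24%)	4965
tubulin, beta 4	21361322	50	4.8	19 (58%)	4879
semenogelin II precursor	4506885	65	9.1	15 (25%)	4205
tubulin, alpha 3c	17921993	50	4.9	15 (56%)	2645
ropporin, rhophilin associated protein 1B	59891409	24	5.1	6 (53%)	2427
prolactin-induced protein	4505821	16	8.2	8 (62%)	2164
A-kinase anchor protein 3	21493041	95	5.8	16 (28%)	1800
outer dense fiber of sperm tails 2 isoform 2	24430183	73	7.2	16 (31%)	1722
sperm protein associated with the nucleus, X chromosome, family member C	13435137	11	5.0	3 (45%)	1437
tubulin alpha 6	14389309	50	4.9	11 (45%)	1374
ropporin	21359920	24	5.5	6 (43%)	1280
clusterin isoform 1	42716297	58	6.2	5 (15%)	1257
sorbitol dehydrogenase	156627571	38	8.2	4 (23%)	1249
beta actin	4501885	42	5.2	6 (34%)	1232
pyruvate kinase, muscle isoform M1	3328642	58	7.6	13 (47%)	1133
histone cluster 1, H2aa	25092737	14	10.8	4 (51%)	1121
mitochondrial ATP synthase beta subunit precursor	32189394	56	5.2	13 (38%)	1031
fatty acid synthase	41872631	275	6.0	10 (9%)	935
glutathione S-transferase mu 3	23065552	26	5.3	7 (32%)	929
histone cluster 1, H2ba	24586679	14	10.3	1 (11%)	823
fibronectin 1 isoform 3 preproprotein	16933542	262	5.4	16 (11%)	790
L-lactate dehydrogenase C	4504973	36	7.0	2 (7%)	693
heat shock 90 kDa protein 1, alpha isoform 2	154146191	85	4.9	10 (18%)	682
glyceraldehyde-3-phosphate dehydrogenase	7669492	36	8.5	3 (15%)	621
sperm autoantigenic protein 17	8394343	17	4.7	2 (22%)	552
triosephosphate isomerase 1 isoform 1	4507645	26	6.4	6 (61%)	530
mitochondrial malate dehydrogenase precursor	21735621	35	8.9	5 (23%)	512
phosphoglycerate kinase 2	31543397	45	8.7	4 (17%)	506
heat shock 70 kDa protein 2	13676857	70	5.5	8 (22%)	423
histone cluster 1, H2ae	10645195	14	11.0	3 (43%)	392
acetyl-Coenzyme A acetyltransferase 1 precursor	4557237	45	8.9	8 (34%)	388
eukaryotic translation elongation factor 1 alpha 1	4503471	50	9.1	7 (30%)	383
ATP synthase, H+ transporting, mitochondrial F1 complex, alpha subunit precursor	4757810	59	9.1	8 (22%)	378
outer dense fiber of sperm tails 1	194248060	30	8.4	3 (22%)	334
voltage-dependent anion channel 2	42476281	32	7.4	3 (19%)	332
acid phosphatase, prostate short isoform precursor	6382064	44	5.8	5 (16%)	326
brain creatine kinase	21536286	42	5.3	7 (29%)	268
saccharopine dehydrogenase (putative)	55770836	47	9.2	4 (29%)	265
protein disulfide-isomerase A3 precursor	21361657	57	5.9	2 (9%)	261
eukaryotic translation elongation factor 2	4503483	96	6.4	3 (8%)	261
heat shock protein 90 kDa beta, member 1	4507677	92	4.7	5 (8%)	250
heat shock protein beta-1	4504517	22	5.9	4 (36%)	191
glutamine synthetase	19923206	42	6.4	3 (14%)	179
valosin-containing protein	6005942	89	5.1	7 (18%)	177
phospholipase A2, group IIA precursor	4505849	16	9.4	2 (23%)	170
tyrosine 3/tryptophan 5-monooxygenase activation protein, zeta polypeptide	4507953	27	4.7	2 (19%)	167
L-lactate dehydrogenase A isoform 1	5031857	36	8.4	2 (7%)	167
fructose-bisphosphate aldolase A	4557305	39	8.3	3 (16%)	167
chaperonin containing TCP1, subunit 5 (epsilon)	24307939	60	5.4	3 (9%)	157
voltage-dependent anion channel 3 isoform b	25188179	30	8.8	4 (26%)	147
peroxiredoxin 6	4758638	25	6.0	4 (33%)	140
glutathione peroxidase 4 isoform A precursor	75709200	22	8.6	5 (43%)	139
transglutaminase 4 (prostate)	156627577	77	6.3	5 (9%)	136
enolase 1	4503571	47	7.0	3 (12%)	134
T-complex protein 1 isoform b	57863259	44	7.5	5 (30%)	129
CSE1 chromosome segregation 1-like protein	29029559	111	5.5	2 (3%)	128
fumarate hydratase precursor	19743875	54	8.8	3 (12%)	115
lectin, mannose-binding 2 precursor	5803023	40	6.4	2 (13%)	115
clathrin heavy chain 1	4758012	193	5.4	6 (7%)	111
chaperonin containing TCP1, subunit 4 (delta)	38455427	58	7.9	4 (19%)	107
RAB2A, member RAS oncogene family	4506365	23	6.0	3 (18%)	106
chromosome 20 open reading frame 3	24308201	46	5.8	3 (19%)	105
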