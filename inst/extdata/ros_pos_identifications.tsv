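protein_name	accession	mw_kda	pi	peptides	mascot_score
A-Kinase anchor protein 4 isoform 2	21493039	94	6.7	34 (54%)	10988
lactotransferrin precursor	54607120	80	8.5	36 (64%)	7287
tubulin, beta, 2	5174735	50	4.7	24 (68%)	6702
tubulin, beta 4	21361322	50	4.8	19 (57%)	5071
glyceraldehyde-3-phosphate dehydrogenase, spermatogenic	7657116	44	8.4	12 (48%)	5711
tubulin, alpha 3c	17921993	50	4.9	15 (51%)	2942
ropporin, rhophilin associated protein 1B	59891409	24	5.1	7 (56%)	2587
semenogelin II precursor	4506885	65	9.1	13 (22%)	2277
outer dense fiber of sperm tails 2 isoform 2	24430183	73	7.2	16 (31%)	2051
semenogelin I isoform a preproprotein	4506883	52	9.3	12 (31%)	1983
sperm protein associated with the nucleus, X chromosome, family member C	13435137	11	5.0	3 (45%)	1892
tubulin, alpha, ubiquitous	57013276	50	4.9	13 (46%)	1616
glutathione S-transferase mu 3	23065552	26	5.3	7 (37%)	1595
prolactin-induced protein	4505821	16	8.2	8 (62%)	1559
A Kinase anchor protein 3	21493041	95	5.8	20 (35%)	1416
histone cluster 1, H2ba	24586679	14	10.3	1 (11%)	1371
mitochondrial malate dehydrogenase precursor	21735621	35	8.9	8 (33%)	1342
histone cluster 1, H2aa	25092737	14	10.8	6 (58%)	1334
clusterin isoform 1	42716297	58	6.2	6 (16%)	1204
ropporin	21359920	24	5.5	6 (43%)	1184
sorbitol dehydrogenase	156627571	38	8.2	7 (35%)	1095
mitochondrial ATP synthase beta subunit precursor	32189394	56	5.2	16 (53%)	976
beta actin	4501885	42	5.2	9 (54%)	909
triosephosphate isomerase 1 isoform 1	4507645	26	6.4	9 (55%)	761
glyceraldehyde-3-phosphate dehydrogenase	7669492	36	8.5	6 (32%)	706
L-lactate dehydrogenase C	4504973	36	7.0	1 (5%)	674
fatty acid synthase	41872631	275	6.0	3 (8%)	669
sperm autoantigenic protein 17	8394343	17	4.7	2 (22%)	592
pyruvate kinase, muscle isoform M2	33286418	58	7.9	11 (38%)	560
ATP synthase, H+ transporting, mitochondrial F1 complex, alpha subunit precursor	4757810	59	9.1	8 (23%)	542
brain creatine kinase	21536286	42	5.3	7 (32%)	511
heat shock protein 90 kDa beta, member 1	4507677	92	4.7	6 (10%)	502
heat shock 70 kDa protein 2	13676857	70	5.5	10 (21%)	448
heat shock 90 kDa protein 1, alpha isoform 1	153792590	98	5.0	8 (13%)	447
saccharopine dehydrogenase (putative)	55770836	47	9.2	5 (29%)	395
actin, alpha 1, skeletal muscle	4501881	42	5.2	6 (36%)	374
glutamine synthetase	19923206	42	6.4	3 (9%)	374
fructose-bisphosphate aldolase A	4557305	39	8.3	5 (29%)	366
eukaryotic translation elongation factor 1 alpha 1	4503471	50	9.1	8 (36%)	347
fibronectin 1 isoform 3 preproprotein	16933542	262	5.4	6 (4%)	321
prostate, ovary, testis expressed protein on chromosome 2	153791352	123	5.8	4 (8%)	317
acetyl-Coenzyme A acetyltransferase 1 precursor	4557237	45	8.9	9 (33%)	316
voltage-dependent anion channel 2	42476281	32	7.4	4 (22%)	293
outer dense fiber of sperm tails 1	194248060	30	8.4	4 (26%)	283
phosphoglycerate kinase 2	31543397	45	8.7	5 (30%)	253
histone cluster 1, H2ae	10645195	14	11.0	4 (49%)	251
protein disulfide-isomerase A3 precursor	21361657	57	5.9	4 (13%)	243
acid phosphatase, prostate short isoform precursor	6382064	44	5.8	5 (16%)	240
voltage-dependent anion channel 3 isoform b	25188179	30	8.8	5 (27%)	226
phospholipase A2, group IIA precursor	4505849	16	9.4	2 (23%)	202
transglutaminase 4 (prostate)	156627577	77	6.3	8 (17%)	187
glutathione peroxidase 4 isoform A precursor	75709200	22	8.6	4 (32%)	181
heat shock 70 kDa protein 5	16507237	72	5.0	4 (8%)	161
heat shock protein beta-1	4504517	22	5.9	3 (31%)	160
angiotensin I converting enzyme 1 isoform 1 precursor	4503273	150	5.9	3 (4%)	160
peroxiredoxin 6	4758638	25	6.0	2 (16%)	145
chaperonin containing TCP1, subunit 5 (epsilon)	24307939	60	5.4	4 (12%)	142
valosin-containing protein	6005942	89	5.1	3 (7%)	142
sperm acrosomal membrane protein 14	19424138	13	5.4	1 (11%)	132
chaperonin containing TCP1, subunit 8 (theta)	48762932	60	5.4	4 (14%)	131
L-lactate dehydrogenase A isoform 1	5031857	36	8.4	2 (13%)	124
phosphoglycerate dehydrogenase	23308577	57	6.2	3 (13%)	112
clathrin heavy chain 1	4758012	193	5.4	4 (5%)	108
chaperonin containing TCP1, subunit 4 (delta)	38455427	58	7.9	5 (21%)	99
peptidylprolyl isomerase A	10863927	18	7.6	2 (23%)	96
fumarate hydratase precursor	19743875	54	8.8	8 (31%)	92
RAB2A, member RAS oncogene family	4506365	23	6.0	3 (18%)	92
olfactomedin 4 precursor	32313593	57	5.5	2 (5%)	90
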