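protein_name	gene_symbol	accession	sc_ros_minus	nsc_ros_minus	sc_ros_plus	nsc_ros_plus	nsc_ratio
acetyl-Coenzyme A acetyltransferase 1 precursor	ACAT1	4557237	20	0.006	26	0.008	1.4
acid phosphatase, prostate short isoform precursor	ACPP	6382064	17	0.005	27	0.009	1.7
actin, alpha 1, skeletal muscle	ACTA1	4501881	0	0.000	8	0.003	ROS+ only
A-kinase anchor protein 3	AKAP3	21493041	76	0.022	70	0.022	1.0
A-kinase anchor protein 4 isoform 2	AKAP4	21493039	497	0.145	467	0.147	1.0
angiotensin I converting enzyme 1 isoform 1 precursor	ACE	4503273	5	0.001	5	0.002	1.1
ATP synthase, H+ transporting, mitochondrial F1 complex, alpha subunit precursor	ATP5A1	4757810	28	0.008	30	0.009	1.2
beta actin	ACTB	4501885	53	0.015	36	0.011	0.7
brain creatine kinase	CKB	21536286	19	0.006	21	0.007	1.2
chaperonin containing TCP1, subunit 4 (delta)	CCT4	38455427	4	0.001	6	0.002	1.6
chaperonin containing TCP1, subunit 5 (epsilon)	CCT5	24307939	4	0.001	7	0.002	1.9
chaperonin containing TCP1, subunit 8 (theta)	CCT8	48762932	5	0.001	4	0.001	0.9
chromosome 20 open reading frame 3	C20orf3	24308201	2	0.001	4	0.001	2.2
clathrin heavy chain 1	CLTC	4758012	14	0.004	6	0.002	0.5
clusterin preproprotein	CLU	355594753	56	0.016	55	0.017	1.1
CSE1 chromosome segregation 1-like protein	CSE1L	29029559	3	0.001	0	0.000	ROS- only
enolase 1	ENO1	4503571	7	0.002	2	0.001	0.3
eukaryotic translation elongation factor 1 alpha 1	EEF1A1	4503471	28	0.008	33	0.010	1.3
eukaryotic translation elongation factor 2	EEF2	4503483	12	0.003	5	0.002	0.5
fatty acid synthase	FASN	41872631	40	0.012	35	0.011	1.0
fibronectin 1 isoform 3 preproprotein	FN1	16933542	41	0.012	21	0.007	0.6
fructose-bisphosphate aldolase A	ALDOA	4557305	15	0.004	17	0.005	1.2
fumarate hydratase precursor	FH	19743875	5	0.001	7	0.002	1.5
glutamine synthetase	GLUL	19923206	4	0.001	12	0.004	3.2
glutathione peroxidase 4 isoform A precursor	GPX4	75709200	8	0.002	21	0.007	2.8
glutathione S-transferase mu 3	GSTM3	23065552	50	0.015	65	0.020	1.4
glyceraldehyde-3-phosphate dehydrogenase	GAPDH	7669492	14	0.004	22	0.007	1.7
glyceraldehyde-3-phosphate dehydrogenase, spermatogenic	GAPDHS	7657116	210	0.061	185	0.058	1.0
heat shock 70 kDa protein 2	HSPA2	13676857	26	0.008	22	0.007	0.9
heat shock 70 kDa protein 5	HSPA5	16507237	5	0.001	11	0.003	2.4
heat shock 90 kDa protein 1, alpha isoform 1	HSP90AA1	153792590	39	0.011	26	0.008	0.7
heat shock protein 90 kDa beta, member 1	HSP90B1	4507677	11	0.003	22	0.007	2.2
heat shock protein beta-1	HSPB1	4504517	5	0.001	4	0.001	0.9
histone cluster 1, H2aa	HIST1H2AA	25092737	47	0.014	56	0.018	1.3
histone cluster 1, H2ae	HISTH1AE	10645195	14	0.004	13	0.004	1.0
histone cluster 1, H2ba	HIST1H2BA	24586679	22	0.006	49	0.015	2.4
lactotransferrin precursor	LTF	54607120	246	0.072	292	0.092	1.3
lectin, mannose-binding 2 precursor	LMAN2	5803023	3	0.001	5	0.002	1.8
L-lactate dehydrogenase A isoform 1	LDHA	5031857	10	0.003	9	0.003	1.0
L-lactate dehydrogenase C	LDHC	4504973	17	0.005	12	0.004	0.8
mitochondrial ATP synthase beta subunit precursor	ATP5B	32189394	50	0.015	70	0.022	1.5
mitochondrial malate dehydrogenase precursor	MDH2	21735621	22	0.006	44	0.014	2.2
olfactomedin 4 precursor	OLFM4	32313593	1	0.000	4	0.001	4.3
outer dense fiber of sperm tails 1	ODF1	194248060	15	0.004	14	0.004	1.0
outer dense fiber of sperm tails 2 isoform 2	ODF2	24430183	90	0.026	91	0.029	1.1
peptidylprolyl isomerase A	PPIA	10863927	4	0.001	2	0.001	0.5
peroxiredoxin 6	PRDX6	4758638	4	0.001	1	0.0003	0.3
phosphoglycerate dehydrogenase	PHGDH	23308577	3	0.001	5	0.002	1.8
phosphoglycerate kinase 2	PGK2	31543397	17	0.005	9	0.003	0.6
phospholipase A2, group IIA precursor	PLA2G2A	4505849	6	0.002	10	0.003	1.8
prolactin-induced protein	PIP	4505821	118	0.034	101	0.032	0.9
prostate specific antigen isoform 1 preproprotein	KLK3	4502173	3	0.001	2	0.001	0.7
protein disulfide-isomerase A3 precursor	PDIA3	21361657	7	0.002	7	0.002	1.1
pyruvate kinase, muscle isoform M2	PKM	33286418	49	0.014	31	0.010	0.7
RAB2A, member RAS oncogene family	RAB2A	4506365	3	0.001	3	0.001	1.1
ropporin	ROPN1	21359920	20	0.006	31	0.010	1.7
ropporin, rhophilin associated protein 1B	ROPN1B	59891409	73	0.021	73	0.023	1.1
saccharopine dehydrogenase (putative)	SCCPDH	55770836	13	0.004	16	0.005	1.3
semenogelin I isoform a preproprotein	SEMG1	4506883	171	0.050	101	0.032	0.6
semenogelin II precursor	SEMG2	4506885	513	0.149	226	0.071	0.5
sorbitol dehydrogenase	SORD	156627571	36	0.010	27	0.009	0.8
sperm acrosomal membrane protein 14	SPACA4	19424138	1	0.000	2	0.001	2.2
sperm autoantigenic protein 17	SPA17	8394343	15	0.004	20	0.006	1.4
sperm protein associated with the nucleus, X chromosome, family member C	SPANX	13435137	54	0.016	80	0.025	1.6
transglutaminase 4 (prostate)	TGM4	156627577	4	0.001	9	0.003	2.4
triosephosphate isomerase 1 isoform 1	TPI1	4507645	28	0.008	31	0.010	1.2
tubulin alpha 6	TUBA1C	14389309	9	0.003	11	0.003	1.3
tubulin, alpha 3c	TUBA3C	17921993	117	0.034	134	0.042	1.2
tubulin, beta 4	TUBB4A	21361322	36	0.010	30	0.009	0.9
tubulin, beta, 2	TUBB4B	5174735	232	0.068	235	0.074	1.1
tyrosine 3/tryptophan 5-monooxygenase activation protein, zeta polypeptide	YWHAZ	4507953	4	0.001	3	0.001	0.8
valosin-containing protein	VCP	6005942	16	0.005	9	0.003	0.6
voltage-dependent anion channel 2	VDAC2	42476281	11	0.003	11	0.003	1.1
voltage-dependent anion channel 3 isoform b	VDAC3	25188179	7	0.002	12	0.004	1.9
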