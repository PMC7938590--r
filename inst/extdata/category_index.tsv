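bit	top_name	short_name	sub_name
0	Agrochemical Information	AgroChemInfo	
1	Agrochemical Information	AgroChemInfo	Agrochemical Category
2	Agrochemical Information	AgroChemInfo	EPA Pesticide Classification
3	Agrochemical Information	AgroChemInfo	FAO/WHO Pesticide Evaluations
4	Agrochemical Information	AgroChemInfo	Pesticide Uses
5	Agrochemical Information	AgroChemInfo	Maximum Residue Limits
6	Agrochemical Information	AgroChemInfo	Reported Fatal Dose
7	Drug and Medication Information	DrugMedicInfo	
8	Drug and Medication Information	DrugMedicInfo	Drug Indication
9	Drug and Medication Information	DrugMedicInfo	Drug Classes
10	Drug and Medication Information	DrugMedicInfo	Clinical Trials
11	Drug and Medication Information	DrugMedicInfo	FDA Approved Drugs
12	Drug and Medication Information	DrugMedicInfo	Therapeutic Uses
13	Drug and Medication Information	DrugMedicInfo	Drug Warnings
14	Food Additives and Ingredients	FoodRelated	
15	Food Additives and Ingredients	FoodRelated	Food Additive Classes
16	Food Additives and Ingredients	FoodRelated	Substances Added to Food
17	Food Additives and Ingredients	FoodRelated	JECFA Evaluations
18	Food Additives and Ingredients	FoodRelated	Associated Foods
19	Pharmacology and Biochemistry	PharmacoInfo	
20	Pharmacology and Biochemistry	PharmacoInfo	Pharmacodynamics
21	Pharmacology and Biochemistry	PharmacoInfo	Mechanism of Action
22	Pharmacology and Biochemistry	PharmacoInfo	Absorption Distribution and Excretion
23	Pharmacology and Biochemistry	PharmacoInfo	Metabolism and Metabolites
24	Pharmacology and Biochemistry	PharmacoInfo	Biological Half-Life
25	Pharmacology and Biochemistry	PharmacoInfo	MeSH Pharmacological Classification
26	Safety and Hazards	SafetyInfo	
27	Safety and Hazards	SafetyInfo	GHS Classification
28	Safety and Hazards	SafetyInfo	Flammability and Explosivity
29	Safety and Hazards	SafetyInfo	Exposure Control
30	Safety and Hazards	SafetyInfo	First Aid Measures
31	Safety and Hazards	SafetyInfo	Transport Information
32	Safety and Hazards	SafetyInfo	Regulatory Information
33	Toxicity	ToxicityInfo	
34	Toxicity	ToxicityInfo	Toxicological Information
35	Toxicity	ToxicityInfo	Acute Effects
36	Toxicity	ToxicityInfo	Carcinogen Classification
37	Toxicity	ToxicityInfo	Ecotoxicity Values
38	Toxicity	ToxicityInfo	Human Toxicity Excerpts
39	Use and Manufacturing	KnownUse	
40	Use and Manufacturing	KnownUse	Uses
41	Use and Manufacturing	KnownUse	Industry Uses
42	Use and Manufacturing	KnownUse	Consumer Uses
43	Use and Manufacturing	KnownUse	Methods of Manufacturing
44	Use and Manufacturing	KnownUse	Production Volumes
45	Use and Manufacturing	KnownUse	Formulations and Preparations
46	Biomolecular Interactions and Pathways	BioPathway	
47	Biomolecular Interactions and Pathways	BioPathway	Metabolic Pathways
48	Biomolecular Interactions and Pathways	BioPathway	Signalling Pathways
49	Biomolecular Interactions and Pathways	BioPathway	Protein Bound Structures
50	Biomolecular Interactions and Pathways	BioPathway	Drug-Gene Interactions
51	Biomolecular Interactions and Pathways	BioPathway	Enzyme Interactions
52	Identification	Identification	
53	Identification	Identification	Record Description
54	Identification	Identification	Synonyms
55	Identification	Identification	Computed Descriptors
56	Identification	Identification	Experimental Spectra
57	Identification	Identification	Other Identifiers
58	Associated Disorders and Diseases	DisorderDisease	
59	Associated Disorders and Diseases	DisorderDisease	Disease Associations
60	Associated Disorders and Diseases	DisorderDisease	Disease Pathways
61	Associated Disorders and Diseases	DisorderDisease	Clinical Significance
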