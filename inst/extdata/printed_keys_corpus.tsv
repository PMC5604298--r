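record_id	key	value
k001	age unit	
k002	age group	
k003	age_years	
k004	age (y)	
k005	age in years	
k006	donor_age	
k007	age (months)	
k008	age (years)	
k009	age (yrs)	
k010	patient age	
k011	age at diagnosis	
k012	age at diagnosis (years)	
k013	age at sample (months)	
k014	patient age (yrs)	
k015	tumor stage	
k016	age.brain	
k017	age (weeks)	
k018	stage	
k019	gestational age (weeks)	
k020	age.blood	
k021	sample age	
k022	age at surgery	
k023	age	
k024	age months	
k025	age(years)	
k026	pathological_stage	
k027	growth/development stage	
k028	growth stage	
k029	pathological stage	
k030	development stage	
k031	cell line name	
k032	cell line source age	
k033	cell line type	
k034	cell lines	
k035	cell line background	
k036	cell lineage	
k037	cell line/clone	
k038	cell line source gender	
k039	cell line source ethnicity	
k040	cell line	
k041	cell line passage	
k042	cell line source	
k043	origin of a cell line	
k044	source cell line	
k045	growth pattern of cell line	
k046	tissue/cell line	
k047	cell line source tissue	
k048	dendritic cell lineages	
k049	coriell cell line repository identifier	
k050	cell line tissue source	
k051	parental cell line	
k052	tumor cell line	
k053	donor cell line	
k054	tissue/cell lines	
k055	injected cell line	
k056	tumour cell line used for conditioning medium	
k057	insect cell line	
k058	cell line origin	
k059	primary cell line	
k060	subject's disease state	
k061	primary disease	
k062	histology (disease state)	
k063	advanced disease stage	
k064	advanced disease state	
k065	disease-state	
k066	meibomian gland disease state	
k067	disease	
k068	disease/treatment status	
k069	disease status of patient	
k070	disease progression	
k071	disease stage	
k072	disease subtype	
k073	status of disease	
k074	clinical characteristic/disease status	
k075	patient disease status	
k076	disease development	
k077	disease phase	
k078	diseased	
k079	disease/cell type	
k080	extent of disease	
k081	disease state	
k082	disease state (host)	
k083	disease severity	
k084	disease_state	
k085	disease model	
k086	disease type	
k087	disease_specific_survival_years	
k088	disease status	
k089	diseasestatus	
k090	disease_specific_survival_event	
k091	disease outcome	
k092	disease exposure	
k093	disease_status	
k094	disease-free survival (dfs)	
k095	disease-free interval (months)	
k096	disease free interval (days)	
k097	disease specific survival (years)	
k098	stage of disease (inss)	
k099	disease relapse (event)	
k100	disease_free_survival_event	
k101	disease-free survival (dfs) event	
k102	disease_free_survival_years	
k103	disease progression (event)	
k104	stage of disease	
k105	disease free interval (months)	
k106	age at disease onset	
k107	duration of disease	
k108	disease free survival in months	
k109	disease free survival time (months)	
k110	background mouse strain	
k111	background/strain	
k112	background strains	
k113	strain	
k114	strain/accession	
k115	strain or line	
k116	strain/background	
k117	strain/genotype	
k118	strain/ecotype	
k119	strains	
k120	strain number	
k121	strain [background]	
k122	strain phenotype	
k123	strain/line	
k124	strain description	
k125	strain source	
k126	strain fgsc number	
k127	strain background (bloomington stock number)	
k128	strain (donor)	
k129	toxoplasma parasite strain	
k130	infection (virus strain)	
k131	human cytomegalovirus strain	
k132	bacteria strain	
k133	siv strain	
k134	viral strain	
k135	recipient strain	
k136	substrain	
k137	parent strain	
k138	parental strain	
k139	host strain	
k140	parasite strain	
k141	host strain background	
k142	maternal strain	
k143	virus strain	
k144	scanstrain	
k145	mice strain	
k146	mouse strain	
k147	plant strain	
k148	sample tissue of origin	
k149	cell/tissue type	
k150	original tissue	
k151	source tissue	
k152	tissue source	
k153	organ/tissue	
k154	original tissue source	
k155	primary tissue	
k156	sample tissue type	
k157	sample type	
k158	cell tissue	
k159	source tissue type	
k160	organ/tissue type	
k161	age of ffpe tissue	
k162	day of tissue dissection	
k163	age at tissue collection (days)	
k164	tissue separation	
k165	tissue & age	
k166	tissuer type	
k167	tissue_detail	
k168	tumor tissue source	
k169	tissue/tumor subtype	
k170	tissue derivation	
k171	tissue	
k172	tissue origination	
k173	tissue site	
k174	tissue_mg	
k175	tumor/tissue type	
k176	tissue subtype	
k177	tissue_biological	
k178	tissue processing	
k179	tissue/development stage	
k180	harvested tissue type	
k181	tissue and developmental stage	
k182	tissue isolated	
k183	pretreatment drug & dose	
k184	pre-treatment	
k185	treatment2_in vivo treatment	
k186	treatment stage	
k187	treatments	
k188	treatment agent	
k189	treatment_molecule	
k190	lighttreatment	
k191	drug treatment time point	
k192	treatment result	
k193	treatment_2	
k194	treatment_1	
k195	tissue treatment	
k196	cactus host treatment	
k197	inducer treatment	
k198	sirna treatment group	
k199	treatment/exposure	
k200	maternal treatment group	
k201	treatment_dose	
k202	treatment dosage	
k203	l-dopa treatment	
k204	patient treatment plan	
k205	nrti treatment status	
k206	culture conditions/treatment	
k207	tamoxifen-citrate treatment	
k208	globin treatment	
k209	experimental treatment	
k210	dopamine-agonists treatment	
k211	oxygen treatment	
k212	tap treatment	
k213	lenolidamide treatment	
k214	time of treatment	
k215	treatment time	
k216	tissue/treatment id	
k217	treatment period	
k218	days after treatment	
k219	treatment duration	
k220	pre-treatment psa	
k221	treatment time (rhgaa)	
k222	weeks of treatment	
k223	tnfa treatment time point	
k224	treatment_time	
k225	treatment length	
k226	time (days post-treatment)	
k227	order of treatment	
k228	bl treatment level	
k229	treatment-time	
k230	time after treatment	
k231	day of dss treatment	
k232	time post treatment	
k233	time of tamoxifen treatment	
k234	h2o2 treatment level	
k235	days of ddc treatment	
k236	weeks after treatment	
k237	post-treatment time	
k238	length of treatment	
k239	duration of il-6 treatment	
k240	treatment start age	
k241	duration of treatment	
k242	days of treatment	
k243	time post-treatment	
k244	treatment age	
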