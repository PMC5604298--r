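age unit	age_a
age group	age_a
age_years	age_a
age (y)	age_a
age in years	age_a
donor_age	age_a
age (months)	age_a
age (years)	age_a
age (yrs)	age_a
patient age	age_a
age at diagnosis	age_a
age at diagnosis (years)	age_a
age at sample (months)	age_a
patient age (yrs)	age_a
tumor stage	age_a
age.brain	age_a
age (weeks)	age_a
stage	age_a
gestational age (weeks)	age_a
age.blood	age_a
sample age	age_a
age at surgery	age_a
age	age_a
age months	age_a
age(years)	age_a
pathological_stage	age_b
growth/development stage	age_b
growth stage	age_b
pathological stage	age_b
development stage	age_b
cell line name	cell_line_a
cell line source age	cell_line_a
cell line type	cell_line_a
cell lines	cell_line_a
cell line background	cell_line_a
cell lineage	cell_line_a
cell line/clone	cell_line_a
cell line source gender	cell_line_a
cell line source ethnicity	cell_line_a
cell line	cell_line_a
cell line passage	cell_line_a
cell line source	cell_line_a
origin of a cell line	cell_line_b
source cell line	cell_line_b
growth pattern of cell line	cell_line_b
tissue/cell line	cell_line_c
cell line source tissue	cell_line_c
dendritic cell lineages	cell_line_c
coriell cell line repository identifier	cell_line_c
cell line tissue source	cell_line_c
parental cell line	cell_line_c
tumor cell line	cell_line_c
donor cell line	cell_line_c
tissue/cell lines	cell_line_c
injected cell line	cell_line_c
tumour cell line used for conditioning medium	cell_line_c
insect cell line	cell_line_c
cell line origin	cell_line_c
primary cell line	cell_line_c
subject's disease state	disease_a
primary disease	disease_a
histology (disease state)	disease_a
advanced disease stage	disease_a
advanced disease state	disease_a
disease-state	disease_b
meibomian gland disease state	disease_b
disease	disease_b
disease/treatment status	disease_b
disease status of patient	disease_b
disease progression	disease_b
disease stage	disease_b
disease subtype	disease_b
status of disease	disease_b
clinical characteristic/disease status	disease_b
patient disease status	disease_b
disease development	disease_b
disease phase	disease_b
diseased	disease_b
disease/cell type	disease_b
extent of disease	disease_b
disease state	disease_b
disease state (host)	disease_b
disease severity	disease_b
disease_state	disease_b
disease model	disease_b
disease type	disease_b
disease_specific_survival_years	disease_c
disease status	disease_c
diseasestatus	disease_c
disease_specific_survival_event	disease_c
disease outcome	disease_c
disease exposure	disease_c
disease_status	disease_c
disease-free survival (dfs)	disease_d
disease-free interval (months)	disease_d
disease free interval (days)	disease_d
disease specific survival (years)	disease_d
stage of disease (inss)	disease_d
disease relapse (event)	disease_d
disease_free_survival_event	disease_d
disease-free survival (dfs) event	disease_d
disease_free_survival_years	disease_d
disease progression (event)	disease_d
stage of disease	disease_d
disease free interval (months)	disease_d
age at disease onset	disease_d
duration of disease	disease_d
disease free survival in months	disease_d
disease free survival time (months)	disease_d
background mouse strain	strain_a
background/strain	strain_a
background strains	strain_a
strain	strain_a
strain/accession	strain_a
strain or line	strain_a
strain/background	strain_a
strain/genotype	strain_a
strain/ecotype	strain_a
strains	strain_a
strain number	strain_a
strain [background]	strain_a
strain phenotype	strain_a
strain/line	strain_a
strain description	strain_a
strain source	strain_a
strain fgsc number	strain_a
strain background (bloomington stock number)	strain_a
strain (donor)	strain_a
toxoplasma parasite strain	strain_b
infection (virus strain)	strain_b
human cytomegalovirus strain	strain_b
bacteria strain	strain_c
siv strain	strain_c
viral strain	strain_c
recipient strain	strain_c
substrain	strain_c
parent strain	strain_c
parental strain	strain_c
host strain	strain_c
parasite strain	strain_c
host strain background	strain_c
maternal strain	strain_c
virus strain	strain_c
scanstrain	strain_c
mice strain	strain_c
mouse strain	strain_c
plant strain	strain_c
sample tissue of origin	tissue_a
cell/tissue type	tissue_a
original tissue	tissue_a
source tissue	tissue_a
tissue source	tissue_a
organ/tissue	tissue_a
original tissue source	tissue_a
primary tissue	tissue_a
sample tissue type	tissue_a
sample type	tissue_a
cell tissue	tissue_a
source tissue type	tissue_a
organ/tissue type	tissue_a
age of ffpe tissue	tissue_b
day of tissue dissection	tissue_b
age at tissue collection (days)	tissue_b
tissue separation	tissue_c
tissue & age	tissue_c
tissuer type	tissue_c
tissue_detail	tissue_c
tumor tissue source	tissue_c
tissue/tumor subtype	tissue_c
tissue derivation	tissue_c
tissue	tissue_c
tissue origination	tissue_c
tissue site	tissue_c
tissue_mg	tissue_c
tumor/tissue type	tissue_c
tissue subtype	tissue_c
tissue_biological	tissue_c
tissue processing	tissue_c
tissue/development stage	tissue_c
harvested tissue type	tissue_c
tissue and developmental stage	tissue_c
tissue isolated	tissue_c
pretreatment drug & dose	treatment_a
pre-treatment	treatment_a
treatment2_in vivo treatment	treatment_a
treatment stage	treatment_a
treatments	treatment_a
treatment agent	treatment_a
treatment_molecule	treatment_a
lighttreatment	treatment_a
drug treatment time point	treatment_a
treatment result	treatment_a
treatment_2	treatment_a
treatment_1	treatment_a
tissue treatment	treatment_a
cactus host treatment	treatment_a
inducer treatment	treatment_a
sirna treatment group	treatment_a
treatment/exposure	treatment_a
maternal treatment group	treatment_a
treatment_dose	treatment_a
treatment dosage	treatment_a
l-dopa treatment	treatment_b
patient treatment plan	treatment_b
nrti treatment status	treatment_b
culture conditions/treatment	treatment_b
tamoxifen-citrate treatment	treatment_b
globin treatment	treatment_b
experimental treatment	treatment_b
dopamine-agonists treatment	treatment_b
oxygen treatment	treatment_b
tap treatment	treatment_b
lenolidamide treatment	treatment_b
time of treatment	treatment_c
treatment time	treatment_c
tissue/treatment id	treatment_c
treatment period	treatment_c
days after treatment	treatment_c
treatment duration	treatment_c
pre-treatment psa	treatment_c
treatment time (rhgaa)	treatment_c
weeks of treatment	treatment_c
tnfa treatment time point	treatment_c
treatment_time	treatment_c
treatment length	treatment_c
time (days post-treatment)	treatment_c
order of treatment	treatment_c
bl treatment level	treatment_c
treatment-time	treatment_c
time after treatment	treatment_c
day of dss treatment	treatment_c
time post treatment	treatment_c
time of tamoxifen treatment	treatment_c
h2o2 treatment level	treatment_c
days of ddc treatment	treatment_c
weeks after treatment	treatment_c
post-treatment time	treatment_c
length of treatment	treatment_c
duration of il-6 treatment	treatment_c
treatment start age	treatment_c
duration of treatment	treatment_c
days of treatment	treatment_c
time post-treatment	treatment_c
treatment age	treatment_c
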