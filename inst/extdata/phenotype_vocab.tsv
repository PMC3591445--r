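tag	source_text	description
microcolony	Microcolony / Micro	arrests as a very slow growing microcolony
brown_pigment	brown	brown pigment produced by colonies or microcolonies
yellow_pigment	Yellow	yellow pigment production
polarity_defect	Polarity defect	defect in establishment of polarized growth
swollen	Swollen	arrests growth as swollen cells
enlarged_vacuoles	Enlarged vacuoles	massively enlarged vacuoles
cell_cycle	Cell cycle	cell cycle defect
short_germling_arrest	Short germling arrest	arrests growth as short germlings
branched_germling_arrest	Branched germling arrest	arrests as thin branched germlings of abnormal morphology
strong_growth_defect	Strong growth defect	strong colony growth defect
moderate_growth_defect	Moderate growth defect	moderate but reproducible colony growth defect
septation_conidiation_defect	-septation and conidiation	septation and conidiation deficient
conidiation_defect	Conidiation defect	reduced asexual spore production
NaCl_sensitive	NaCl^s	growth inhibition in the presence of NaCl
NaCl_remedial	NaCl^Rem	defects remediated on NaCl
sucrose_sensitive	Suc^s	growth inhibition in the presence of 1.5 M sucrose
sucrose_remedial	Suc^Rem	defects remediated on sucrose
HU_sensitive	HU	hydroxyurea sensitive
DEO_sensitive	DEO	DEO (DNA alkylating agent) sensitive
camptothecin_sensitive	Camp	camptothecin sensitive
benomyl_sensitive	Ben	benomyl sensitive
colony_color	Colony color	abnormal colony color
increased_pigment	Increased pigment production	increased pigment production
early_sexual_development	Early sexual development	premature onset of sexual development
arrested_sexual_development	Arrested sexual development	sexual development arrested before cleistothecia mature
early_incomplete_sexual_development	Early but incomplete sexual development	early onset but arrest at nascent cleistothecia
early_septation	Early septation	premature septum formation
variable_phenotype	V	variability in phenotype
heterokaryons_recovered	Het	heterokaryons also recovered among primary transformants
nulls_not_generated	Nulls not generated from heterokaryons	heterokaryons did not yield kinase-deleted conidia; terminal phenotype undefined
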