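systematic_id	name	group_path	deletion_status	phenotypes	is_ffk
AN4238	SchA	AGC/Akt	viable		FALSE
AN5973	PkcB	AGC/Akt	lethal	microcolony	FALSE
AN5529	CotA	AGC/NDR	lethal	microcolony;brown_pigment;polarity_defect	FALSE
AN10485	An-Stk21	AGC/NDR	viable		FALSE
AN7572	SrrB	AGC/NDR	viable	NaCl_sensitive	FALSE
AN8751	SidB	AGC/NDR	viable	strong_growth_defect;septation_conidiation_defect;NaCl_sensitive	FALSE
AN3110	An-Ksg1	AGC/PDK1	lethal	microcolony	FALSE
AN4717	PkaB	AGC/PKA	viable		FALSE
AN6305	PkaA	AGC/PKA	viable	strong_growth_defect;sucrose_remedial;NaCl_remedial	FALSE
AN0106	PkcA	AGC/PKC/PKC	lethal	swollen	FALSE
AN4980	An-Psk1	AGC/RSK	viable		FALSE
AN0144	An-Nrc2	AGC/RSK	viable	moderate_growth_defect	FALSE
AN7537	An-Ppk33	AGC/YANK	viable	NaCl_sensitive	FALSE
AN2412	CmkA	CAMK/CAMK1	viable	moderate_growth_defect;increased_pigment	FALSE
AN3065	CmkB	CAMK/CAMK1	viable		FALSE
AN4483	CmkD	CAMK/CAMK1	viable		FALSE
AN7695	An-Snf1	CAMK/CAMKL/AMPK	viable		FALSE
AN5494	ChkA	CAMK/CAMKL/CHK1	viable	HU_sensitive;DEO_sensitive	FALSE
AN11101	An-Gin4	CAMK/CAMKL/GIN4	viable	early_sexual_development	FALSE
AN1171	An-Kin1	CAMK/CAMKL/Kin1	viable	moderate_growth_defect	FALSE
AN0822	KfsA	CAMK/CAMKL/Kin4	viable	moderate_growth_defect	FALSE
AN5759	An-Stk19	CAMK/CAMKL/MARK	viable		FALSE
AN4536	An-Psk1	CAMK/CAMKL/PASK	viable		FALSE
AN6347	An-Stk26	CAMK/CAMK-Unique	viable		FALSE
AN7737	An-Mek1	CAMK/CAMK-Unique	viable		FALSE
AN1097	An-Nnk1	CAMK/CAMK-Unique	viable		FALSE
AN4279	ChkB	CAMK/RAD53	viable	HU_sensitive	FALSE
AN7563	ChkC	CAMK/RAD53	viable	HU_sensitive	FALSE
AN4563	CkiA	CK1/CK1/CK1-D	lethal	short_germling_arrest	FALSE
AN5757	CkiB	CK1/CK1/CK1-G	viable	strong_growth_defect	FALSE
AN0699	An-Cak1	CMGC/CDK/CDC2	viable	strong_growth_defect;heterokaryons_recovered	FALSE
AN4182	NimX	CMGC/CDK/CDC2	lethal	cell_cycle	FALSE
AN1867	PhoB	CMGC/CDK/CDK5	viable		FALSE
AN8261	PhoA	CMGC/CDK/CDK5	viable	NaCl_sensitive	FALSE
AN8285	An-Cdk7	CMGC/CDK/CDK7	lethal	swollen;enlarged_vacuoles	FALSE
AN2489	An-Ssn3	CMGC/CDK/CDK8	viable	moderate_growth_defect	FALSE
AN8865	PtkA	CMGC/CDK	viable	strong_growth_defect;NaCl_sensitive	FALSE
AN8190	An-Stk47	CMGC/CDK/CRK7	viable	strong_growth_defect;NaCl_sensitive	FALSE
AN6044	NpkA	CMGC/CDK	viable		FALSE
AN1485	An-Cka1	CMGC/CK2	lethal	microcolony	FALSE
AN0988	An-Lkh1	CMGC/CLK	viable	strong_growth_defect	FALSE
AN4936	An-Prp4	CMGC/DYRK/PRP4	lethal	short_germling_arrest;swollen	FALSE
AN7104	An-Yak1	CMGC/DYRK/YAK	viable	moderate_growth_defect;yellow_pigment	FALSE
AN7678	An-Pom1	CMGC/DYRK/YAK	viable		FALSE
AN6508	An-Gsk3	CMGC/GSK	viable	strong_growth_defect;brown_pigment;conidiation_defect;sucrose_remedial	FALSE
AN1017	HogA	CMGC/MAPK/ERK	viable	NaCl_sensitive	FALSE
AN3719	MpkB	CMGC/MAPK/ERK	viable	moderate_growth_defect;arrested_sexual_development	FALSE
AN4668	MpkC	CMGC/MAPK/ERK	viable		FALSE
AN5666	MpkA	CMGC/MAPK/ERK	viable	branched_germling_arrest;NaCl_remedial;sucrose_remedial	FALSE
AN6243	ImeB	CMGC/RCK/MAK	viable	moderate_growth_defect	FALSE
AN7185	SrpkA	CMGC/SRPK	viable	moderate_growth_defect;NaCl_sensitive	FALSE
AN10895	SrpkB	CMGC/SRPK	viable		FALSE
AN1315	SrpkC	CMGC/SRPK	viable		FALSE
AN10325	SrpkD	CMGC/SRPK	viable		FALSE
AN10937	SrpkE	CMGC/SRPK	viable		FALSE
AN10082	SrpkF	CMGC/SRPK	viable		FALSE
AN10462	SrpkG	CMGC/SRPK	viable		FALSE
AN5815	An-Aurora	Other/Aur	lethal	nulls_not_generated	FALSE
AN3946	SldA	Other/BUB	viable	moderate_growth_defect;benomyl_sensitive;NaCl_sensitive;colony_color	FALSE
AN5728	An-Stk22	Other/CAMKK/ELM	viable		FALSE
AN8827	CmkC	Other/CAMKK/ELM	viable	NaCl_sensitive	FALSE
AN3450	An-Cdc7	Other/CDC7	lethal	cell_cycle;swollen	FALSE
AN10019	An-Oca2	Other/HAL	viable		FALSE
AN2943	RfeA	Other/HAL	viable		FALSE
AN8830	HalA	Other/HAL	viable	moderate_growth_defect;NaCl_sensitive	FALSE
AN2054	An-Haspin	Other/Haspin	viable		FALSE
AN1665	An-Stk51	Other/IKS	viable		FALSE
AN0235	IreA	Other/IRE	lethal	swollen	FALSE
AN10515	An-Prk1	Other/NAK/NAK	viable	strong_growth_defect	FALSE
AN10193	An-Env7	Other/NAK	viable		FALSE
AN9504	NimA	Other/NEK/NEK2	lethal	cell_cycle	FALSE
AN2246	An-Gcn2	Other/PEK/GCN2	viable		FALSE
AN7321	An-HriA	Other/PEK/HRI	viable		FALSE
AN1560	PlkA	Other/PLK	viable	strong_growth_defect;early_sexual_development;NaCl_sensitive	FALSE
AN2265	An-Ksp1	Other/RAN	viable		FALSE
AN4935	An-Ran1	Other/RAN	viable		FALSE
AN4322	An-Scy1	Other/SCY1	viable		FALSE
AN2927	An-Mps1	Other/TTK	lethal	nulls_not_generated	FALSE
AN1632	An-Atg1	Other/ULK/ULK	viable		FALSE
AN0576	An-Vps15	Other/VPS15	lethal	microcolony	FALSE
AN3001	An-Isr1	Other/Other-Unique	viable		FALSE
AN5822	An-Wee1	Other/WEE	lethal	cell_cycle	FALSE
AN4385	SepH	STE/STE11/CDC15	lethal	strong_growth_defect;septation_conidiation_defect;NaCl_sensitive;heterokaryons_recovered	FALSE
AN10153	SskB	STE/STE11/STE11	viable	NaCl_sensitive;sucrose_sensitive	FALSE
AN2269	SteC	STE/STE11	viable	moderate_growth_defect;arrested_sexual_development	FALSE
AN4887	BckA	STE/STE11	lethal	branched_germling_arrest;NaCl_remedial;sucrose_remedial	FALSE
AN6339	An-Pod6	STE/STE20	lethal	microcolony;brown_pigment;polarity_defect	FALSE
AN2067	An-Ste20	STE/STE20/PAKA	viable	increased_pigment	FALSE
AN8836	An-Cla4	STE/STE20/PAKA	viable	strong_growth_defect	FALSE
AN11032	SepL	STE/STE20/YSK	viable	strong_growth_defect;septation_conidiation_defect;NaCl_sensitive	FALSE
AN5674	An-Mst1	STE/STE20/YSK	viable	early_incomplete_sexual_development	FALSE
AN0931	PbsA	STE/STE7/STE7	viable	NaCl_sensitive;sucrose_sensitive	FALSE
AN3422	Ste7	STE/STE7	viable	moderate_growth_defect;arrested_sexual_development	FALSE
AN4189	MkkA	STE/STE7	lethal	branched_germling_arrest;NaCl_remedial;sucrose_remedial	FALSE
AN7986	FfkA	Unclassified/Ank	viable		TRUE
AN10819	FfkB	Unclassified/Ank	viable		TRUE
AN2373	FfkC	Unclassified/Ank	viable		TRUE
AN1789	FfkD	Unclassified	viable		TRUE
AN10869	FfkE	Unclassified	viable		TRUE
AN4196	FfkF	Unclassified	viable		TRUE
AN6192	FfkG	Unclassified	viable		TRUE
AN5511	FfkH	Unclassified	viable		TRUE
AN6768	FfkI	Unclassified	viable		TRUE
AN6758	FfkJ	Unclassified	not_determined		TRUE
AN9302	FfkK	Unclassified	not_determined		TRUE
AN10800	PkpA	Atypical/PDHK	viable		FALSE
AN9461	PkpB	Atypical/PDHK	not_determined		FALSE
AN6207	PkpC	Atypical/PDHK	viable		FALSE
AN4278	An-Stt4	Atypical/PIKK	lethal_kinase_domain	microcolony;variable_phenotype;cell_cycle	FALSE
AN4709	An-Vps34	Atypical/PIKK	lethal	microcolony	FALSE
AN10791	An-Lsb6	Atypical/PIKK	viable	strong_growth_defect;heterokaryons_recovered	FALSE
AN0038	AtmA	Atypical/PIKK/ATM	viable	camptothecin_sensitive	FALSE
AN6975	UvsB	Atypical/PIKK/ATR	viable	moderate_growth_defect;HU_sensitive;DEO_sensitive;camptothecin_sensitive;colony_color	FALSE
AN5982	TorA	Atypical/PIKK/FRAP	lethal	short_germling_arrest;early_septation	FALSE
AN6363	SudD	Atypical/RIO/RIO1	lethal	short_germling_arrest;swollen	FALSE
AN0124	An-Rio2	Atypical/RIO/RIO2	lethal	short_germling_arrest	FALSE
AN5296	TcsA	Atypical/HisK	viable		FALSE
AN1800	TcsB	Atypical/HisK	viable		FALSE
AN7945	hk-2	Atypical/HisK	viable		FALSE
AN2581	hk-8-1	Atypical/HisK	viable		FALSE
AN4113	hk-8-2	Atypical/HisK	viable		FALSE
AN6820	hk-8-3	Atypical/HisK	viable		FALSE
AN4818	hk-8-4	Atypical/HisK	viable		FALSE
AN3214	hk-8-5	Atypical/HisK	viable		FALSE
AN2363	hk-8-6	Atypical/HisK	viable		FALSE
AN9048	hk-8-7	Atypical/HisK	viable		FALSE
AN4447	hk-9	Atypical/HisK	viable		FALSE
AN4479	NikA	Atypical/HisK	viable	strong_growth_defect	FALSE
AN3102	PhkA	Atypical/HisK	viable_kinase_domain		FALSE
AN3101	PhkB	Atypical/HisK	viable		FALSE
AN9008	FphA	Atypical/HisK	viable		FALSE
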