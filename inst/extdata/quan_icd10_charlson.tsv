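# ICD-10 coding algorithm for Charlson comorbidities, after Quan et al. 2005
# (Med Care 43:1130-9, Table 1), restricted to the 13 conditions handled by
# this package: malignancy, metastatic tumour, dementia and AIDS/HIV are
# excluded by design.  Weights are the original Charlson et al. 1987 weights.
# Prefixes are normalized (uppercase, dot removed); a code matches a condition
# when the prefix is a leading substring of the normalized code.
condition	prefix	weight
myocardial_infarction	I21	1
myocardial_infarction	I22	1
myocardial_infarction	I252	1
congestive_heart_failure	I099	1
congestive_heart_failure	I110	1
congestive_heart_failure	I130	1
congestive_heart_failure	I132	1
congestive_heart_failure	I255	1
congestive_heart_failure	I420	1
congestive_heart_failure	I425	1
congestive_heart_failure	I426	1
congestive_heart_failure	I427	1
congestive_heart_failure	I428	1
congestive_heart_failure	I429	1
congestive_heart_failure	I43	1
congestive_heart_failure	I50	1
congestive_heart_failure	P290	1
peripheral_vascular	I70	1
peripheral_vascular	I71	1
peripheral_vascular	I731	1
peripheral_vascular	I738	1
peripheral_vascular	I739	1
peripheral_vascular	I771	1
peripheral_vascular	I790	1
peripheral_vascular	I792	1
peripheral_vascular	K551	1
peripheral_vascular	K558	1
peripheral_vascular	K559	1
peripheral_vascular	Z958	1
peripheral_vascular	Z959	1
cerebrovascular	G45	1
cerebrovascular	G46	1
cerebrovascular	H340	1
cerebrovascular	I60	1
cerebrovascular	I61	1
cerebrovascular	I62	1
cerebrovascular	I63	1
cerebrovascular	I64	1
cerebrovascular	I65	1
cerebrovascular	I66	1
cerebrovascular	I67	1
cerebrovascular	I68	1
cerebrovascular	I69	1
chronic_pulmonary	I278	1
chronic_pulmonary	I279	1
chronic_pulmonary	J40	1
chronic_pulmonary	J41	1
chronic_pulmonary	J42	1
chronic_pulmonary	J43	1
chronic_pulmonary	J44	1
chronic_pulmonary	J45	1
chronic_pulmonary	J46	1
chronic_pulmonary	J47	1
chronic_pulmonary	J60	1
chronic_pulmonary	J61	1
chronic_pulmonary	J62	1
chronic_pulmonary	J63	1
chronic_pulmonary	J64	1
chronic_pulmonary	J65	1
chronic_pulmonary	J66	1
chronic_pulmonary	J67	1
chronic_pulmonary	J684	1
chronic_pulmonary	J701	1
chronic_pulmonary	J703	1
rheumatic	M05	1
rheumatic	M06	1
rheumatic	M315	1
rheumatic	M32	1
rheumatic	M33	1
rheumatic	M34	1
rheumatic	M351	1
rheumatic	M353	1
rheumatic	M360	1
peptic_ulcer	K25	1
peptic_ulcer	K26	1
peptic_ulcer	K27	1
peptic_ulcer	K28	1
liver_mild	B18	1
liver_mild	K700	1
liver_mild	K701	1
liver_mild	K702	1
liver_mild	K703	1
liver_mild	K709	1
liver_mild	K713	1
liver_mild	K714	1
liver_mild	K715	1
liver_mild	K717	1
liver_mild	K73	1
liver_mild	K74	1
liver_mild	K760	1
liver_mild	K762	1
liver_mild	K763	1
liver_mild	K764	1
liver_mild	K768	1
liver_mild	K769	1
liver_mild	Z944	1
diabetes_uncomplicated	E100	1
diabetes_uncomplicated	E101	1
diabetes_uncomplicated	E106	1
diabetes_uncomplicated	E108	1
diabetes_uncomplicated	E109	1
diabetes_uncomplicated	E110	1
diabetes_uncomplicated	E111	1
diabetes_uncomplicated	E116	1
diabetes_uncomplicated	E118	1
diabetes_uncomplicated	E119	1
diabetes_uncomplicated	E120	1
diabetes_uncomplicated	E121	1
diabetes_uncomplicated	E126	1
diabetes_uncomplicated	E128	1
diabetes_uncomplicated	E129	1
diabetes_uncomplicated	E130	1
diabetes_uncomplicated	E131	1
diabetes_uncomplicated	E136	1
diabetes_uncomplicated	E138	1
diabetes_uncomplicated	E139	1
diabetes_uncomplicated	E140	1
diabetes_uncomplicated	E141	1
diabetes_uncomplicated	E146	1
diabetes_uncomplicated	E148	1
diabetes_uncomplicated	E149	1
diabetes_complicated	E102	2
diabetes_complicated	E103	2
diabetes_complicated	E104	2
diabetes_complicated	E105	2
diabetes_complicated	E107	2
diabetes_complicated	E112	2
diabetes_complicated	E113	2
diabetes_complicated	E114	2
diabetes_complicated	E115	2
diabetes_complicated	E117	2
diabetes_complicated	E122	2
diabetes_complicated	E123	2
diabetes_complicated	E124	2
diabetes_complicated	E125	2
diabetes_complicated	E127	2
diabetes_complicated	E132	2
diabetes_complicated	E133	2
diabetes_complicated	E134	2
diabetes_complicated	E135	2
diabetes_complicated	E137	2
diabetes_complicated	E142	2
diabetes_complicated	E143	2
diabetes_complicated	E144	2
diabetes_complicated	E145	2
diabetes_complicated	E147	2
hemiplegia_paraplegia	G041	2
hemiplegia_paraplegia	G114	2
hemiplegia_paraplegia	G801	2
hemiplegia_paraplegia	G802	2
hemiplegia_paraplegia	G81	2
hemiplegia_paraplegia	G82	2
hemiplegia_paraplegia	G830	2
hemiplegia_paraplegia	G831	2
hemiplegia_paraplegia	G832	2
hemiplegia_paraplegia	G833	2
hemiplegia_paraplegia	G834	2
hemiplegia_paraplegia	G839	2
renal	I120	2
renal	I131	2
renal	N032	2
renal	N033	2
renal	N034	2
renal	N035	2
renal	N036	2
renal	N037	2
renal	N052	2
renal	N053	2
renal	N054	2
renal	N055	2
renal	N056	2
renal	N057	2
renal	N18	2
renal	N19	2
renal	N250	2
renal	Z490	2
renal	Z491	2
renal	Z492	2
renal	Z940	2
renal	Z992	2
liver_moderate_severe	I850	3
liver_moderate_severe	I859	3
liver_moderate_severe	I864	3
liver_moderate_severe	I982	3
liver_moderate_severe	K704	3
liver_moderate_severe	K711	3
liver_moderate_severe	K721	3
liver_moderate_severe	K729	3
liver_moderate_severe	K765	3
liver_moderate_severe	K766	3
liver_moderate_severe	K767	3
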