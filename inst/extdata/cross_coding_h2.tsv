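self_reported_disease	h2_self_reported	icd10_code	h2_icd10
Breast cancer	0.133	C50 Malignant neoplasm of breast	0.207
Skin cancer	0.061	C43-C44 Melanoma and other malignant neoplasms of skin	0.160
Male genital tract cancer	0.226	C60-C63 Malignant neoplasms of male genital organs	0.322
Prostate cancer	0.310	C61 Malignant neoplasm of prostate	0.426
Cerebrovascular disease	0.066	I60-I69 Cerebrovascular diseases	0.197
Angina	0.176	I20 Angina pectoris	0.136
Liver/Biliary/Pancreas problem	0.074	K80-K87 Disorders of gallbladder, biliary tract and pancreas	0.099
Heart attack/Myocardial infarction	0.184	I21 Acute myocardial infarction	0.193
Gastro-oesophageal reflux (gord)/Gastric reflux	0.099	K21 Gastro-oesophageal reflux disease	0.105
Cholelithiasis/Gall stones	0.123	K80 Cholelithiasis	0.143
Uterine fibroids	0.087	D25 Leiomyoma of uterus	0.054
Enlarged prostate	0.157	N40 Hyperplasia of prostate	0.127
Pneumonia	0.075	J18 Pneumonia-organism unspecified	0.160
Diverticular disease/Diverticulitis	0.195	K57 Diverticular disease of intestine	0.179
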