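pt_code	pt_name	soc_code	soc_name	primary_soc
90000001	Gastrooesophageal reflux disease	10017947	Gastrointestinal disorders	TRUE
90000002	Dyspepsia	10017947	Gastrointestinal disorders	TRUE
90000003	Incorrect dose administered	10022117	Injury, poisoning and procedural complications	TRUE
90000004	Vomiting	10017947	Gastrointestinal disorders	TRUE
90000005	Blood glucose abnormal	10022891	Investigations	TRUE
90000006	Injection site haemorrhage	10018065	General disorders and administration site conditions	TRUE
90000007	Increased appetite	10027433	Metabolism and nutrition disorders	TRUE
90000008	Inappropriate schedule of product administration	10022117	Injury, poisoning and procedural complications	TRUE
90000009	Injection site pain	10018065	General disorders and administration site conditions	TRUE
90000010	Thyroid hormones increased	10022891	Investigations	TRUE
90000011	Eructation	10017947	Gastrointestinal disorders	TRUE
90000012	Glycosylated haemoglobin abnormal	10022891	Investigations	TRUE
90000013	Accidental underdose	10022117	Injury, poisoning and procedural complications	TRUE
90000014	Pancreatitis	10017947	Gastrointestinal disorders	TRUE
90000015	Injection site paraesthesia	10018065	General disorders and administration site conditions	TRUE
90000016	Blood glucose increased	10022891	Investigations	TRUE
90000017	Injection site injury	10018065	General disorders and administration site conditions	TRUE
90000018	Diabetic retinopathy	10015919	Eye disorders	TRUE
90000019	Hunger	10018065	General disorders and administration site conditions	TRUE
90000020	Product administered at inappropriate site	10022117	Injury, poisoning and procedural complications	TRUE
90000021	Product prescribing error	10022117	Injury, poisoning and procedural complications	TRUE
90000022	Counterfeit product administered	10022117	Injury, poisoning and procedural complications	TRUE
90000023	Impaired gastric emptying	10017947	Gastrointestinal disorders	TRUE
90000024	Wrong patient received product	10022117	Injury, poisoning and procedural complications	TRUE
90000025	Starvation	10027433	Metabolism and nutrition disorders	TRUE
90000026	Abdominal rigidity	10017947	Gastrointestinal disorders	TRUE
90000027	Feeding disorder	10027433	Metabolism and nutrition disorders	TRUE
90000028	Injection site urticaria	10018065	General disorders and administration site conditions	TRUE
90000029	Nausea	10017947	Gastrointestinal disorders	TRUE
90000030	Abdominal distension	10017947	Gastrointestinal disorders	TRUE
90000031	Abdominal pain upper	10017947	Gastrointestinal disorders	TRUE
90000032	Injection site bruising	10018065	General disorders and administration site conditions	TRUE
90000033	Thyroid mass	10014698	Endocrine disorders	TRUE
90000034	Blood glucose fluctuation	10022891	Investigations	TRUE
90000035	Weight decreased	10022891	Investigations	TRUE
90000035	Weight decreased	10027433	Metabolism and nutrition disorders	FALSE
90000036	Injection site discolouration	10018065	General disorders and administration site conditions	TRUE
90000037	Food craving	10027433	Metabolism and nutrition disorders	TRUE
90000038	Medullary thyroid cancer	10029104	Neoplasms benign, malignant and unspecified (incl cysts and polyps)	TRUE
90000039	Injection site erythema	10018065	General disorders and administration site conditions	TRUE
90000040	Decreased appetite	10027433	Metabolism and nutrition disorders	TRUE
90000041	Off label use	10022117	Injury, poisoning and procedural complications	TRUE
90000042	Appetite disorder	10027433	Metabolism and nutrition disorders	TRUE
90000043	Hypoglycaemia	10027433	Metabolism and nutrition disorders	TRUE
90000044	Injection site rash	10018065	General disorders and administration site conditions	TRUE
90000045	Injection site discomfort	10018065	General disorders and administration site conditions	TRUE
90000046	Injection site pruritus	10018065	General disorders and administration site conditions	TRUE
90000047	Headache	10029205	Nervous system disorders	TRUE
90000048	Diarrhoea	10017947	Gastrointestinal disorders	TRUE
90000049	Constipation	10017947	Gastrointestinal disorders	TRUE
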