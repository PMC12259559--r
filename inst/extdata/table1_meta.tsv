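cohort_id	accession	tissue	population	n_case	n_control
GSE65682	GSE65682	whole_blood	US adult cohort	761	41
GSE28750	GSE28750	whole_blood	Australian adult cohort	21	20
GSE57065	GSE57065	whole_blood	French adult cohort	82	25
GSE95233	GSE95233	whole_blood	French adult cohort	102	22
GSE69528	GSE69528	whole_blood	US and Thai adult cohort	83	55
GSE131761	GSE131761	whole_blood	Spanish adult cohort	81	15
GSE154918	GSE154918	whole_blood	Australian and German adult cohort	65	40
GSE13904	GSE13904	whole_blood	US children cohort	209	18
GSE9692	GSE9692	whole_blood	US children cohort	45	15
GSE49757	GSE49757	plasma	US adult cohort	37	19
selfcollected	self-collected	plasma	Chinese adult cohort	32	18
GSE9960	GSE9960	pbmc	Australian cohort	54	16
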