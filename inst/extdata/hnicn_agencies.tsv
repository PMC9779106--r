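code	canonical_name	aliases	prefix	middle	tagged	category
A1	National Health Commission of the People's Republic of China	NHC;National Health Commission	National	Health	Commission	government-department
A2	Ministry of Civil Affairs of the People's Republic of China	MCA;Ministry of Civil Affairs		Civil Affairs	Ministry	government-department
A3	National Development and Reform Commission	NDRC	National	Development and Reform	Commission	government-department
A4	Ministry of Education of the People's Republic of China	MOE;Ministry of Education		Education	Ministry	government-department
A5	Ministry of Finance of the People's Republic of China	MOF;Ministry of Finance		Finance	Ministry	government-department
A6	Ministry of Human Resources and Social Security of the People's Republic of China	MHRSS		Human Resources and Social Security	Ministry	government-department
A7	Ministry of Natural Resources of the People's Republic of China	MNR		Natural Resources	Ministry	government-department
A8	Ministry of Housing and Urban-Rural Development of the People's Republic of China	MOHURD		Housing and Urban-Rural Development	Ministry	government-department
A9	State Administration for Market Regulation	SAMR	State	Market Regulation	Administration	government-department
A10	National Healthcare Security Administration	NHSA	National	Healthcare Security	Administration	government-department
A11	National Administration of Traditional Chinese Medicine	NATCM	National	Traditional Chinese Medicine	Administration	government-department
A12	China National Committee on Aging	CNCA	China National	Aging	Committee	government-department
A13	Ministry of Agriculture and Rural Affairs of the People's Republic of China	MARA		Agriculture and Rural Affairs	Ministry	government-department
A14	Ministry of Industry and Information Technology of the People's Republic of China	MIIT;Ministry of Industry and Information Technology		Industry and Information Technology	Ministry	government-department
A15	People's Bank of China	PBC	People's	China	Bank	government-department
A16	State Taxation Administration	STA	State	Taxation	Administration	government-department
A17	China Banking and Insurance Regulatory Commission	CBIRC	China	Banking and Insurance Regulatory	Commission	government-department
A18	China Securities Regulatory Commission	CSRC	China	Securities Regulatory	Commission	government-department
A19	Ministry of Emergency Management of the People's Republic of China	MEM		Emergency Management	Ministry	government-department
B1	Central Committee of the Communist Youth League of China	CCCYL	Central	Communist Youth League	Committee	public-organization
B2	All-China Women's Federation	ACWF	All-China	Women's	Federation	public-organization
B3	Red Cross Society of China	RCS		Red Cross	Society	public-organization
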