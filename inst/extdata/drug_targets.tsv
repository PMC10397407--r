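drug_class	substance	drugbank_id	genes
Statins	Atorvastatin	DB01076	HMGCR; DPP4; AHR; HDAC2; NR1I3
Statins	Fluvastatin	DB01095	HMGCR; HDAC2
Statins	Pravastatin sodium	DB00175	HMGCR; HDAC2
Statins	Rosuvastatin	DB01098	HMGCR; ITGAL
Statins	Simvastatin	DB00641	HMGCR; ITGAL; HDAC2
Statins	Lovastatin	DB00227	HMGCR; ITGAL
Statins	Alirocumab	DB09302	PCSK9
Statins	Fish oil	DB13961	DGAT2; PTGS2; FFAR4
Statins	Pitavastatin	DB08860	HMGCR; ITGAL
Ezetimibe	Ezetimibe	DB00973	NPC1L1; SOAT1; ANPEP
Fibrates	Bezafibrate	DB01393	PPARA; PPARD; PPARG; NR1I2; RXRA; RXRB; RXRG
Fibrates	Ciprofibrate	DB09064	PPARA
Fibrates	Fenofibrate	DB01039	PPARA; MMP25; NR1I2
Fibrates	Gemfibrozil	DB01241	PPARA; SLCO1B1; SLC22A8; SLCO2B1; SLCO1B3
Fibrates	Fenofibric acid	DB13873	PPARA; MMP25; PPARG; PPARD; NR1I2
Nicotinic acid group	Acipimox	DB09055
Nicotinic acid group	Nicotinic acid	DB00627	HCAR3; HCAR2; QPRT; NNMT
Omega-3 fatty acid compounds	Omega-3-acid ethyl esters	DB09539	SREBF1
Omega-3 fatty acid compounds	Omega-3-carboxylic acids	DB09568	DGAT2; HSD17B10; ECHS1; HADH; ELOVL4; LPL
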