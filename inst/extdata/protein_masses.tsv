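peak_mz	name	accession	mass_lo_da	mass_hi_da
2434	Stress-70 protein, mitochondrial	GRP_Human	2433.01	2434.25
2434	Protein disulfide-isomerase	PDIA1_Human	2433.01	2434.25
2434	Desmoplakin	DESP_Human	2433.01	2434.25
2434	Exportin-2	XPO2_Human	2433.01	2434.25
2434	Translocator protein	TSPOA_Human	2433.01	2434.25
2434	Mucin-2	MUC2_Human	2433.01	2434.25
2434	Voltage-dependent anion-selective channel protein 1	VDAC1_Human	2433.01	2434.25
2434	Glutamine-fructose-6-phosphate amidotransferase 1	GFPT1_Human	2433.01	2434.25
2434	Eukaryotic translation initiation factor 2 subunit alpha	IF2A_Human	2433.01	2434.25
2434	Heterogeneous nuclear ribonucleoproteins A2/B1	ROA2_Human	2433.01	2434.25
2434	Transketolase	TKT_Human	2433.01	2434.25
2434	Protein S100-A1	S10A1_Human	2433.01	2434.25
2434	Adipocyte enhancer-binding protein 1	AEBP1_Human	2433.01	2434.25
2434	Ezrin	EZRI_Human	2433.01	2434.25
3008	Ras GTPase-activating-like protein IQGAP1	IQGA1_Human	3007.48	3008.60
3008	Glutathione S-transferase P	GSTP1_Human	3007.48	3008.60
3008	2',3'-cyclic-nucleotide 3'-phosphodiesterase	CN37_Human	3007.48	3008.60
3008	Collagen alpha-1(XII) chain	COCA1_Human	3007.48	3008.60
3334	Major vault protein	MVP_Human	3334.65	3334.74
3334	Ig gamma-1 chain C region	IGHG1_Human	3334.65	3334.74
3334	IGHV4-31 protein	A0A087WSY4_Human	3334.65	3334.74
3376	14-3-3 protein sigma	1433S_Human	3376.60	3376.60
3448	Tubulin alpha-1C chain	Q8N532_Human	3448.64	3448.66
3448	Collagen alpha-1(VI) chain	CO6A1_Human	3448.64	3448.66
3448	Tubulin alpha-1B chain	TBA1B_Human	3448.64	3448.66
2395	Eosinophil peroxidase	PERE_Human	2394.05	2395.32
2395	Tubulin beta-4B chain	TBB4B_Human	2394.05	2395.32
2395	Epiplakin	EPIPL_Human	2394.05	2395.32
2395	Cullin-3	CUL3_Human	2394.05	2395.32
2395	Prolow-density lipoprotein receptor-related protein 1	LRP1_Human	2394.05	2395.32
2395	Extended synaptotagmin-1	ESYT1_Human	2394.05	2395.32
2395	Transgelin	TAGL_Human	2394.05	2395.32
2395	DNA-dependent protein kinase catalytic subunit	PRKDC_Human	2394.05	2395.32
2395	Peroxisomal acyl-coenzyme A oxidase 1	ACOX1_Human	2394.05	2395.32
2395	Protein deglycase DJ-1	PARK7_Human	2394.05	2395.32
2395	Lactotransferrin	TRFL_Human	2394.05	2395.32
2395	Protein enabled homolog	ENAH_Human	2394.05	2395.32
2395	Transgelin-2	TAGL2_Human	2394.05	2395.32
2395	Tubulin protein	Q9BUU9_Human	2394.05	2395.32
4761	Thymosin beta-4	TYB4_Human	4761.42	4761.42
4977	Thymosin beta-4	TYB4_Human	4977.49	4977.49
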