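id	chrom	pos	trait	effect	maf	pve
SNP_72835	chr8	1844855	18:3_SD_NA	0.876	0.130	14.08
SNP_151966	chr14	31754793	18:3_SD_NA	-1.165	0.054	24.04
SNP_187379	chr19	7626530	18:3_SD_NA	-1.035	0.127	21.85
SNP_78439	chr8	19496871	18:3_SD_HN	1.320	0.099	24.34
SNP_79026	chr8	20320858	18:3_SD_HN	-0.703	0.335	18.84
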