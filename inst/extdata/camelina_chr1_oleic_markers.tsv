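id	chrom	pos	trait	effect	maf	pve
SNP_591	chr1	2611818	18:2_PM_LN	-0.930	0.110	9.90
SNP_653	chr1	2712622	18:1_SD_LN	1.027	0.0896	57.77
INDEL_458_1	chr1	3063926	18:1_PM_HN	1.318	0.117	35.18
SNP_739	chr1	3125731	18:1_SD_HN	0.852	0.101	51.55
SNP_742	chr1	3148736	18:1_SD_LN	1.197	0.075	52.80
INDEL_480	chr1	3198922	18:2_PM_LN	0.808	0.150	3.83
SNP_753	chr1	3225897	18:1_BZ_NA	0.596	0.126	23.75
SNP_754	chr1	3226206	18:1_BZ_NA	0.620	0.133	25.65
INDEL_483	chr1	3230709	18:1_PM_NA	1.131	0.088	10.53
SNP_763	chr1	3247468	18:2_PM_NA	-1.673	0.076	29.76
SNP_1392	chr1	5000540	18:1_BZ_NA	0.968	0.0744	61.13
SNP_1558	chr1	5899218	18:2_PM_LN	-0.934	0.138	14.65
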