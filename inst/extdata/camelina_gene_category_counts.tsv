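marker_set	total_genes	PROTEIN_DIFF_4PLUS	PROTEIN_DIFF_1TO3	SILENT_CDS	NONCODING_ONLY	NO_MATCH_OR_NO_DIFF
all_fatty_acid_markers	2676	880	507	144	806	339
chr1_oleic_marker_set	254	56	61	24	101	12
snp_1392_region	33	4	3	5	20	1
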