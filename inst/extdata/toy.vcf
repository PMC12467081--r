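##fileformat=VCFv4.2
##contig=<ID=chr1>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	acc1	acc2	acc3
chr1	100	s1	A	T	.	PASS	.	GT	0/1	0/0	1/1
chr1	250	s2	C	CTT	.	PASS	.	GT	./.	0|1	0/0
chr1	400	s3	G	A,T	.	PASS	.	GT	0/1	1/2	0/0
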