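##fileformat=VCFv4.2
##contig=<ID=chr1,length=200000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2
chr1	10000	out_d5	AAAAAA	A	50	PASS	.	GT	0/1	1/1
chr1	11000	out_d12	AAAAAAAAAAAAA	A	50	PASS	.	GT	1/1	0/0
chr1	12000	out_i20	A	ACCCCCCCCCCCCCCCCCCCC	50	PASS	.	GT	0/0	1/1
chr1	13000	out_d3	AAAA	A	50	PASS	.	GT	1/1	1/1
chr1	14000	out_d25	AAAAAAAAAAAAAAAAAAAAAAAAAA	A	50	PASS	.	GT	0/1	0/0
chr1	51000	in_d3	AAAA	A	50	PASS	.	GT	1/1	0/0
chr1	52000	in_d5	AAAAAA	A	50	PASS	.	GT	1/1	0/0
chr1	53000	in_i12	A	ACCCCCCCCCCCC	50	PASS	.	GT	0/1	1/1
chr1	54000	in_d20	AAAAAAAAAAAAAAAAAAAAA	A	50	PASS	.	GT	1/1	./.
chr1	55000	in_d25	AAAAAAAAAAAAAAAAAAAAAAAAAA	A	50	PASS	.	GT	0/0	1/1
chr1	56000	in_snv	A	G	50	PASS	.	GT	1/1	0/1
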