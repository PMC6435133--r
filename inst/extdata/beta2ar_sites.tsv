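# beta-2 adrenergic receptor worked-example site map (10 bi-allelic SNPs).
# Genomic positions are synthetic placeholders (1 kb spacing); alleles are
# the wild/rare pairs of the worked example.
index	chrom	pos	wild	rare
1	b2AR	1000	G	A
2	b2AR	2000	C	A
3	b2AR	3000	G	A
4	b2AR	4000	C	G
5	b2AR	5000	T	C
6	b2AR	6000	T	C
7	b2AR	7000	T	C
8	b2AR	8000	G	A
9	b2AR	9000	C	G
10	b2AR	10000	G	A
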