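##fileformat=VCFv4.2
##source=larvascan synthetic fixture (hand-written example genotypes)
##contig=<ID=contig1>
##contig=<ID=contig2>
##INFO=<ID=NS,Number=1,Type=Integer,Description="Number of samples">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	FEMALE1	MALE1
contig1	100	m1	A	G	50	PASS	NS=2	GT:DP	0/0:55	1/1:60
contig1	200	m2	A	G	50	PASS	NS=2	GT:DP	0/1:50	1/1:45
contig1	300	m3	C	T	50	PASS	NS=2	GT:DP	1/1:80	0/0:90
contig1	400	m4	A	AT	50	PASS	NS=2	GT:DP	0/0:50	1/1:50
contig1	500	m5	A	G,T	50	PASS	NS=2	GT:DP	0/0:50	1/1:50
contig1	600	m6	G	A	50	PASS	NS=2	GT	0/0	1/1
contig1	700	m7	A	G	50	PASS	NS=2	GT:DP	0/0:30	1/1:100
contig2	100	m8	T	C	50	PASS	NS=2	GT:DP	./.:10	1/1:50
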