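##fileformat=VCFv4.2
##source=migrascan_toy_fixture
##contig=<ID=toy_scaf,length=10000>
##INFO=<ID=DP,Number=1,Type=Integer,Description="Raw read depth">
##INFO=<ID=MQ,Number=1,Type=Float,Description="Average mapping quality">
##INFO=<ID=RPBZ,Number=1,Type=Float,Description="Read position bias Z-score">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Per-sample read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3	s4	s5
toy_scaf	100	.	A	G	50	PASS	DP=20;MQ=50;RPBZ=0.5	GT:DP	0/0:10	0/1:10	1/1:10	0/1:10	0/0:10
toy_scaf	200	.	C	T	20	PASS	DP=20;MQ=50;RPBZ=0.5	GT:DP	0/0:10	0/1:10	0/1:10	0/0:10	0/0:10
toy_scaf	300	.	G	A	50	PASS	DP=5;MQ=50;RPBZ=0.5	GT:DP	0/0:10	0/1:10	0/1:10	0/0:10	0/0:10
toy_scaf	400	.	T	C	50	PASS	DP=45;MQ=50;RPBZ=0.5	GT:DP	0/0:10	0/1:10	0/1:10	0/0:10	0/0:10
toy_scaf	500	.	A	C	50	PASS	DP=20;MQ=30;RPBZ=0.5	GT:DP	0/0:10	0/1:10	0/1:10	0/0:10	0/0:10
toy_scaf	600	.	G	T	50	PASS	DP=20;MQ=50;RPBZ=-3	GT:DP	0/1:10	0/1:10	1/1:10	0/0:10	0/0:10
toy_scaf	700	.	C	A	50	PASS	DP=20;MQ=50;RPBZ=3.5	GT:DP	0/0:10	0/1:10	0/1:10	0/0:10	0/0:10
toy_scaf	800	.	A	T	50	PASS	DP=20;MQ=50;RPBZ=0.5	GT:DP	0/1:3	1/1:4	0/1:10	0/0:10	0/0:10
toy_scaf	900	.	T	G	50	PASS	DP=20;MQ=50;RPBZ=0.5	GT:DP	./.:10	./.:10	0/1:10	0/0:10	0/0:10
toy_scaf	1000	.	C	G	50	PASS	DP=20;MQ=50;RPBZ=0.5	GT:DP	./.:10	0/1:10	0/1:10	0/0:10	0/0:10
toy_scaf	1100	.	G	C	50	PASS	DP=20;MQ=50;RPBZ=0.5	GT:DP	0/0:10	0/1:10	1/1:10	0/0:10	0/0:10
toy_scaf	1200	.	A	C,T	50	PASS	DP=20;MQ=50;RPBZ=0.5	GT:DP	0/0:10	0/1:10	0/2:10	0/0:10	0/0:10
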