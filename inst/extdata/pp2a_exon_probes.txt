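probe	sequence
1	ccgagcgatctatcaatcag
2	gacatcctcaccaaaactca
3	tcgggtataaaggctcatca
4	tagctcgtcgataagcacag
5	ccaagagcacgagcaatgat
6	atcaactcttttcttgtcct
7	catcgtcattgttctcacta
8	atagccaaaagcacctcatc
9	atacagaataaaacccccca
10	caagtttcctcaacagtgga
11	tcatctgagcaccaattcta
12	tagccagaggagtgaaatgc
13	cattcaccagctgaaagtcg
14	ggaaaatcccacatgctgat
15	atattgatcttagctccgtc
16	attggcatgtcatcttgaca
17	aaattagttgctgcagctct
18	gctgattcaattgtagcagc
19	ccgaatcttgatcatcttgc
20	caaccctcaacagccaataa
21	ctccaacaatttcccaagag
22	caaccatataacgcacacgc
23	agtagacgagcatatgcagg
24	gaacttctgcctcattatca
25	cacagggaagaatgtgctgg
26	tgacgtgctgagaagagtct
27	cccattataactgatgccaa
28	tggttcacttggtcaagttt
29	tctacaatggctggcagtaa
30	cgattatagccagacgtact
31	gactggccaacaagggaata
32	catcaaagaagcctacacct
33	ttgcatgcaaagagcaccaa
34	acggattgagtgaaccttgt
35	cttcagattgtttgcagcag
36	ggaccaaactcttcagcaag
37	ggaactatatgctgcattgc
38	gtgggttgttaatcatctct
39	tgcacgaagaatcgtcatcc
40	ttactggagcgagaagcga
41	ctctgtctttagatgcagtt
42	gaacatgtgatctcggatcc
43	catcattttggccacgttaa
44	cgtatcatgttctccacaac
45	atcaacatctgggtcttcac
46	ttggagagcttgatttgcga
47	acacaattcgttgctgtctt
48	cgcccaacgaacaaatcaca
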