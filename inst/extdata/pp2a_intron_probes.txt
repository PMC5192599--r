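probe	sequence
1	actattaccattcttagact
2	gaactgaaactttgtgccgt
3	tgacccattagcctctaaaa
4	ctttaaactcaattccgcct
5	tgcatacatagacaccatca
6	gtaaaccagccttatctaac
7	ttgacagagcatggaaagga
8	tcttctgttttagtggctta
9	acaattgacaaaggacccca
10	gcatatttccaaactttggg
11	acacctataaggggaacact
12	acttcaacctaccaatttcc
13	atgttctcttagatcaacca
14	aaagagcgctaaagccagag
15	tcacatacacaaccacaacc
16	acctataccgaggtatgtat
17	gcttaagtcggtttcacatt
18	acacaatgacagtgttcagt
19	cccataactaggcttgatga
20	acttgcctattacacatcag
21	tgttcaatgcagtaacccta
22	gcttaacttcagctaatggt
23	agctgagatgtagacaaccg
24	ctttcccataaagctcatca
25	agcagctcatacatatctgc
26	aacttcaaccatcactgctt
27	acctctgaagtcagtaatct
28	catggacttccaagtaccaa
29	cacactcttcttaagtgtgt
30	tggtcctttgcataatatga
31	cttagcaaacaccgacagta
32	ctacgtgtagatttataggt
33	atcggtttttaattctgctt
34	gtattcatgatatgagaggc
35	cactccaaactatagagcca
36	atctttatctctaagatgct
37	gatgacagtgactaggacga
38	ccttccaggcacagttaaaa
39	acatagtgaggttttcttat
40	atgccaagttaaaagctgca
41	gagtaacttggtcaatagca
42	acccaatgtcgtacaaagag
43	acagctcctttgaacatgtg
44	tagtcattgacttgaccaaa
45	ggacaaagaatttgctgtca
46	ctggatgattcaatgaaggt
47	ttcaagcagtagagacgaca
48	actccaataaccaatagcta
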