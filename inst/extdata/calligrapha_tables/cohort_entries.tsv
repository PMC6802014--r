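count	st1	st2	haplotype	taxon	flag
11			B1	C. m. bigsbyana	
1			B6	C. m. bigsbyana	
2			B14	C. m. bigsbyana	
1			B15	C. m. bigsbyana	
2			B18	C. m. bigsbyana	
2			B31	C. m. bigsbyana	
1			B32	C. m. bigsbyana	
2			B33	C. m. bigsbyana	
1			B35	C. m. bigsbyana	
5			B46	C. m. bigsbyana	
3			B47	C. m. bigsbyana	
1			B48	C. m. bigsbyana	
3			B57	C. m. bigsbyana	
2			B58	C. m. bigsbyana	
6			U5	C. m. bigsbyana	
1			U7	C. m. bigsbyana	
6			U8	C. m. bigsbyana	
1			B27	C. philadelphica	
4			B28	C. philadelphica	
1			B29	C. philadelphica	
3			B59	C. philadelphica	
1			B69	C. philadelphica	
1			B73	C. philadelphica	
9			U1	C. philadelphica	
1			U2	C. philadelphica	
2			U3	C. philadelphica	
1			U4	C. philadelphica	
1			U13	C. philadelphica	
4			U3	C. vicina	
4			U5	C. suturella	
13	wCallA1		B1	C. m. bigsbyana	
1	wCallA1		B12	C. m. bigsbyana	
2	wCallA1		B18	C. m. bigsbyana	
1	wCallA1		B38	C. m. bigsbyana	
1	wCallA1		B45	C. m. bigsbyana	
1	wCallA1		B46	C. m. bigsbyana	
16	wCallA1		B49	C. m. bigsbyana	
1	wCallA1		B54	C. m. bigsbyana	
3	wCallA1		B63	C. philadelphica	
6	wCallA1		U1	C. philadelphica	
4	wCallA1		U9	C. philadelphica	
2	wCallA1		U10	C. philadelphica	
4	wCallA1		U11	C. philadelphica	
2	wCallA1		U12	C. philadelphica	
1	wCallA1		U13	C. philadelphica	
2	wCallA1		U3	C. vicina	
1	wCallA1		U5	C. suturella	
3	wCallA2		B1	C. philadelphica	
1	wCallA2		B7	C. philadelphica	
23	wCallA2		B14	C. m. bigsbyana	
1	wCallA3		B39	C. m. bigsbyana	
1	wCallA3		B40	C. m. bigsbyana	
1	wCallA3		B41	C. m. bigsbyana	
1	wCallA4		B1	C. m. bigsbyana	
2	wCallB1		B14	C. multipunctata	
8	wCallB1		B33	C. multipunctata	
2	wCallB1		B34	C. multipunctata	
2	wCallB1		B35	C. multipunctata	
2	wCallB1		B36	C. multipunctata	
1	wCallB2		B33	C. multipunctata	
2	wCallB2		B34	C. multipunctata	
2	wCallB2		B35	C. multipunctata	
1	wCallB2		B56	C. multipunctata	
3	wCallC2		B59	C. philadelphica	
3	wCallC2		B68	C. philadelphica	
1	wCallA1	wCallA6	B63	C. philadelphica	
1	wCallA1	wCallB1	B1	C. philadelphica	
1	wCallA1	wCallB1	B7	C. philadelphica	
1	wCallA1	wCallB1	B26	C. philadelphica	
13	wCallA1	wCallB1	B29	C. philadelphica	
1	wCallA1	wCallB1	B63	C. philadelphica	
1	wCallA1	wCallB1	B64	C. philadelphica	
6	wCallA1	wCallB1	U1	C. philadelphica	
1	wCallA1	wCallB1	B8	C. m. bigsbyana	
4	wCallA1	wCallB1	B9	C. m. bigsbyana	
1	wCallA1	wCallB1	B10	C. m. bigsbyana	
4	wCallA1	wCallB1	B11	C. m. bigsbyana	
1	wCallA1	wCallB1	B13	C. m. bigsbyana	
2	wCallA1	wCallB1	B16	C. m. bigsbyana	
10	wCallA1	wCallB1	B24	C. m. bigsbyana	
1	wCallA1	wCallB1	B25	C. m. bigsbyana	
1	wCallA1	wCallB1	B37	C. m. bigsbyana	
8	wCallA1	wCallB1	B42	C. m. bigsbyana	
1	wCallA1	wCallB1	B44	C. m. bigsbyana	
25	wCallA1	wCallB1	B49	C. m. bigsbyana	
2	wCallA1	wCallB1	B50	C. m. bigsbyana	
1	wCallA1	wCallB1	B51	C. m. bigsbyana	
1	wCallA1	wCallB1	B52	C. m. bigsbyana	
10	wCallA1	wCallB1	B53	C. m. bigsbyana	
1	wCallA1	wCallB1	B55	C. m. bigsbyana	
1	wCallA1	wCallB1	U3	C. vicina	
1	wCallA1	wCallB3	B49	C. m. bigsbyana	
1	wCallA1	wCallB4	B29	C. philadelphica	
68	wCallA1	wCallC1	B1	C. m. bigsbyana	
1	wCallA1	wCallC1	B2	C. m. bigsbyana	
1	wCallA1	wCallC1	B3	C. m. bigsbyana	
1	wCallA1	wCallC1	B5	C. m. bigsbyana	
40	wCallA1	wCallC1	B18	C. m. bigsbyana	
1	wCallA1	wCallC1	B19	C. m. bigsbyana	
1	wCallA1	wCallC1	B20	C. m. bigsbyana	
1	wCallA1	wCallC1	B21	C. m. bigsbyana	
1	wCallA1	wCallC1	U5	C. suturella	
1	wCallA1	wCallC1	U6	C. suturella	
15	wCallA1	wCallC2	B59	C. philadelphica	
1	wCallA1	wCallC2	B60	C. philadelphica	
1	wCallA1	wCallC2	B61	C. philadelphica	
3	wCallA1	wCallC2	B62	C. philadelphica	
3	wCallA1	wCallC2	B65	C. philadelphica	
1	wCallA1	wCallC2	B66	C. philadelphica	
1	wCallA1	wCallC2	B71	C. philadelphica	
1	wCallA1	wCallC2	B72	C. philadelphica	
1	wCallA1	wCallC2	U1	C. philadelphica	
2	wCallA1	wCallC3	B1	C. m. bigsbyana	
1	wCallA1	wCallC3	B18	C. m. bigsbyana	
1	wCallA1	wCallC4	B65	C. philadelphica	
1	wCallA1	wCallC5	B4	C. philadelphica	
4	wCallA2	wCallB1	B1	C. philadelphica	
1	wCallA2	wCallB1	B7	C. philadelphica	
1	wCallA2	wCallB1	B22	C. philadelphica	
1	wCallA2	wCallB1	B23	C. philadelphica	
2	wCallA2	wCallB1	B26	C. philadelphica	
7	wCallA2	wCallB1	B27	C. philadelphica	
7	wCallA2	wCallB1	B28	C. philadelphica	
2	wCallA2	wCallB1	B30	C. philadelphica	
6	wCallA2	wCallB1	B14	C. m. bigsbyana	
5	wCallA2	wCallB1	B17	C. m. bigsbyana	
4	wCallA2	wCallC2	B71	C. philadelphica	
1	wCallA4	wCallC1	B1	C. m. bigsbyana	
1	wCallA5	wCallB4	B29	C. philadelphica	
2	wCallA5	wCallB4	U1	C. philadelphica	
1	wCallA5	wCallC1	B1	C. m. bigsbyana	
3	wCallA6	wCallC2	B67	C. philadelphica	
1	wCallA6	wCallC2	B70	C. philadelphica	
2	wCallA1	wCallB1r	B42	C. m. bigsbyana	
1	wCallA1	wCallB1r	B43	C. m. bigsbyana	
1	wCallB1	wCallC1	B18	C. m. bigsbyana	uncertain
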