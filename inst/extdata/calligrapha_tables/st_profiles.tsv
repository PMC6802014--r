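ST	gatB	coxA	hcpA	ftsZ	fbpA	group	provenance	variant
wCallA1	a	33	42	32	36	wCallA	observed	FALSE
wCallA2	b	33	42	32	36	wCallA	observed	FALSE
wCallA3	b	33	42	32	d	wCallA	observed	FALSE
wCallA4	a	33	42	32	e	wCallA	observed	FALSE
wCallB1	c	33	c	b	b	wCallB	observed	FALSE
wCallB2	c	33	c	32	b	wCallB	observed	FALSE
wCallC2	d	33	b	75	c	wCallC	observed	FALSE
wCallA5	a	33	42	b	36	wCallA	deduced	FALSE
wCallA6	a	33	b	32	36	wCallA	deduced	FALSE
wCallB3	c	33	b	b	b	wCallB	deduced	FALSE
wCallB4	c	33	c	75	b	wCallB	deduced	FALSE
wCallC1	d	b	b	75	c	wCallC	deduced	FALSE
wCallC3	d	b	b	75	b	wCallC	deduced	FALSE
wCallC4	d	33	b	75	b	wCallC	deduced	FALSE
wCallC5	d	33	c	b	b	wCallC	deduced	FALSE
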