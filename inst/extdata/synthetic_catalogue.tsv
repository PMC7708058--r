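# synthetic detectable-site catalogue for the synthetic_cI reporter
position	change_class	ref_base	alt_base	weight
19	indel	.	.	1
19	substitution	A	.	1
20	indel	.	.	1
20	substitution	C	.	1
21	indel	.	.	1
21	substitution	C	.	1
22	indel	.	.	1
22	substitution	T	.	1
23	indel	.	.	1
23	substitution	G	.	1
24	indel	.	.	1
24	substitution	G	.	1
25	indel	.	.	1
25	substitution	C	.	1
26	indel	.	.	1
26	substitution	C	.	1
27	indel	.	.	1
27	substitution	T	.	1
28	indel	.	.	1
28	substitution	C	.	1
29	indel	.	.	1
29	substitution	G	.	1
30	indel	.	.	1
30	substitution	T	.	1
31	indel	.	.	1
31	substitution	C	.	1
32	indel	.	.	1
32	substitution	T	.	1
33	indel	.	.	1
33	substitution	T	.	1
34	indel	.	.	1
34	substitution	C	.	1
35	indel	.	.	1
35	substitution	A	.	1
36	indel	.	.	1
36	substitution	T	.	1
37	indel	.	.	1
37	substitution	T	.	1
38	indel	.	.	1
38	substitution	A	.	1
39	indel	.	.	1
39	substitution	A	.	1
40	indel	.	.	1
40	substitution	G	.	1
41	indel	.	.	1
41	substitution	C	.	1
42	indel	.	.	1
42	substitution	C	.	1
43	indel	.	.	1
43	substitution	G	.	1
44	indel	.	.	1
44	substitution	A	.	1
45	indel	.	.	1
45	substitution	G	.	1
46	indel	.	.	1
46	substitution	G	.	1
47	indel	.	.	1
47	substitution	C	.	1
48	indel	.	.	1
48	substitution	A	.	1
49	indel	.	.	1
49	substitution	G	.	1
50	indel	.	.	1
50	substitution	G	.	1
51	indel	.	.	1
51	substitution	A	.	1
52	indel	.	.	1
52	substitution	G	.	1
53	indel	.	.	1
53	substitution	C	.	1
54	indel	.	.	1
54	substitution	G	.	1
55	indel	.	.	1
55	substitution	A	.	1
56	indel	.	.	1
56	substitution	C	.	1
57	indel	.	.	1
57	substitution	T	.	1
58	indel	.	.	1
58	substitution	T	.	1
59	indel	.	.	1
59	substitution	T	.	1
60	indel	.	.	1
60	substitution	A	.	1
61	indel	.	.	1
61	substitution	G	.	1
62	indel	.	.	1
62	substitution	A	.	1
63	indel	.	.	1
63	substitution	C	.	1
64	indel	.	.	1
64	substitution	A	.	1
65	indel	.	.	1
65	substitution	C	.	1
66	indel	.	.	1
66	substitution	T	.	1
340	indel	.	.	1
340	substitution	T	.	0.3
341	indel	.	.	1
341	substitution	A	.	0.3
342	indel	.	.	1
342	substitution	C	.	0.3
343	indel	.	.	1
343	substitution	A	.	0.3
344	indel	.	.	1
344	substitution	C	.	0.3
345	indel	.	.	1
345	substitution	C	.	0.3
346	indel	.	.	1
346	substitution	C	.	0.3
347	indel	.	.	1
347	substitution	C	.	0.3
348	indel	.	.	1
348	substitution	A	.	0.3
349	indel	.	.	1
349	substitution	C	.	0.3
350	indel	.	.	1
350	substitution	G	.	0.3
351	indel	.	.	1
352	indel	.	.	1
353	indel	.	.	1
354	indel	.	.	1
355	indel	.	.	1
356	indel	.	.	1
357	indel	.	.	1
358	indel	.	.	1
359	indel	.	.	1
360	indel	.	.	1
361	indel	.	.	1
362	indel	.	.	1
363	indel	.	.	1
364	indel	.	.	1
365	indel	.	.	1
366	indel	.	.	1
367	indel	.	.	1
368	indel	.	.	1
369	indel	.	.	1
370	indel	.	.	1
371	indel	.	.	1
372	indel	.	.	1
373	indel	.	.	1
374	indel	.	.	1
375	indel	.	.	1
376	indel	.	.	1
377	indel	.	.	1
378	indel	.	.	1
379	indel	.	.	1
380	indel	.	.	1
381	indel	.	.	1
382	indel	.	.	1
383	indel	.	.	1
384	indel	.	.	1
385	indel	.	.	1
386	indel	.	.	1
387	indel	.	.	1
388	indel	.	.	1
389	indel	.	.	1
390	indel	.	.	1
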