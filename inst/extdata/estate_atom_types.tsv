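index	type
1	sLi
2	ssBe
3	ssssBe
4	ssBH
5	sssB
6	ssssB
7	sCH3
8	dCH2
9	ssCH2
10	tCH
11	dsCH
12	aaCH
13	sssCH
14	ddC
15	tsC
16	dssC
17	aasC
18	aaaC
19	ssssC
20	sNH3
21	sNH2
22	ssNH2
23	dNH
24	ssNH
25	aaNH
26	tN
27	sssNH
28	dsN
29	aaN
30	sssN
31	ddsN
32	aasN
33	ssssN
34	sOH
35	dO
36	ssO
37	aaO
38	sF
39	sSiH3
40	ssSiH2
41	sssSiH
42	ssssSi
43	sPH2
44	ssPH
45	sssP
46	dsssP
47	sssssP
48	sSH
49	dS
50	ssS
51	aaS
52	dssS
53	ddssS
54	sCl
55	sGeH3
56	ssGeH2
57	sssGeH
58	ssssGe
59	sAsH2
60	ssAsH
61	sssAs
62	sssdAs
63	sssssAs
64	sSeH
65	dSe
66	ssSe
67	aaSe
68	dssSe
69	ddssSe
70	sBr
71	sSnH3
72	ssSnH2
73	sssSnH
74	ssssSn
75	sI
76	sPbH3
77	ssPbH2
78	sssPbH
79	ssssPb
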