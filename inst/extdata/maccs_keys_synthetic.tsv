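key	kind	arg1	arg2	min
1	element	C		1
2	element	C		2
3	element	C		4
4	element	C		8
5	element	C		16
6	element	N		1
7	element	N		2
8	element	N		4
9	element	O		1
10	element	O		2
11	element	O		4
12	element	O		8
13	element	S		1
14	element	S		2
15	element	P		1
16	element	F		1
17	element	F		2
18	element	Cl		1
19	element	Cl		2
20	element	Br		1
21	element	I		1
22	element	B		1
23	element	Si		1
24	element	Na		1
25	element	K		1
26	element	Li		1
27	element	Ca		1
28	element	Mg		1
29	element	Zn		1
30	element	Fe		1
31	halogen			1
32	hetero			1
33	hetero			4
34	hydrogen_total			1
35	hydrogen_total			4
36	hydrogen_total			8
37	hydrogen_total			16
38	ringsize		3	1
39	ringsize		4	1
40	ringsize		5	1
41	ringsize		6	1
42	ringsize		7	1
43	ringsize		8	1
44	ringsize		6	2
45	ringsize		5	2
46	ringcount			1
47	ringcount			2
48	ringcount			3
49	aromring			1
50	aromring			2
51	satring			1
52	heteroring		5	1
53	nring_size		5	1
54	oring_size		5	1
55	heteroring		6	1
56	nring_size		6	1
57	oring_size		6	1
58	carbonring		6	1
59	charge_pos			1
60	charge_neg			1
61	degree	C	3	1
62	degree	C	4	1
63	degree	N	3	1
64	degree	N	4	1
65	hcount	O	1	1
66	hcount	N	1	1
67	hcount	N	2	1
68	hcount	C	3	1
69	hcount	S	1	1
70	hcount	C	2	1
71	chain	C=O		1
72	chain	C-O		1
73	chain	C-N		1
74	chain	C=N		1
75	chain	C#N		1
76	chain	C-S		1
77	chain	C=S		1
78	chain	S=O		1
79	chain	N-O		1
80	chain	N=O		1
81	chain	P=O		1
82	chain	P-O		1
83	chain	C-F		1
84	chain	C-Cl		1
85	chain	C-Br		1
86	chain	C-I		1
87	chain	N-N		1
88	chain	O-O		1
89	chain	S-S		1
90	chain	C=C		1
91	chain	C#C		1
92	chain	c:c		1
93	chain	c:n		1
94	chain	c:o		1
95	chain	c:s		1
96	chain	O=C-O		1
97	chain	O=C-N		1
98	chain	O=C-C		1
99	chain	N-C-N		1
100	chain	O-C-O		1
101	chain	C-O-C		1
102	chain	C-N-C		1
103	chain	C-S-C		1
104	chain	C-C-C		1
105	chain	N-C=N		1
106	chain	O=S=O		1
107	chain	O=P-O		1
108	chain	C=C-C=O		1
109	chain	C-C=O		1
110	chain	N-C-C		1
111	chain	O-C-C		1
112	chain	S-C-C		1
113	chain	c-C		1
114	chain	c-N		1
115	chain	c-O		1
116	chain	c-X		1
117	chain	c-c		1
118	chain	O=C-c		1
119	chain	N-c		1
120	chain	O-c		1
121	chain	C-C-N		1
122	chain	C-C-O		1
123	chain	C-C=C		1
124	chain	N=C-N		1
125	chain	O-C=O		1
126	chain	Q-Q		1
127	chain	Q-Q-Q		1
128	chain	X-C-X		1
129	chain	A#A		1
130	chain	A=A-A=A		1
131	chain	O=C-C=O		1
132	chain	N-N=O		1
133	chain	C=N-O		1
134	chain	c:c:c:c		1
135	chain	C-C-C-C		1
136	chain	C-C-C-O		1
137	chain	C-C-C-N		1
138	chain	O-C-C-O		1
139	chain	N-C-C-N		1
140	chain	O-C-C-N		1
141	chain	C~N~C~N		1
142	chain	S-C=N		1
143	chain	C=C-C		1
144	chain	C-C-S		1
145	chain	N~C~O		1
146	chain	Q~C~Q		1
147	chain	X~A~X		1
148	chain	A-A=A		1
149	chain	C-Si		1
150	chain	B-O		1
151	chain	Se-C		1
152	chain	As-O		1
153	chain	Cl~Cl		1
154	chain	Br~Br		1
155	chain	I~I		1
156	chain	F~F		1
157	chain	P~N		1
158	chain	P~S		1
159	chain	S~N		1
160	chain	B~C		1
161	chain	Si~O		1
162	chain	Si~C		1
163	chain	N#C-C		1
164	chain	O=C-S		1
165	chain	S=C-N		1
166	chain	Q~A~A~Q		1
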