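# Default bHLH consensus profile (synthetic stand-in encoding the published
# 19-conserved-residue layout: basic 5, helix1 5, loop 1, helix2 8).
# Columns: index, region, allowed_residues ('*' = any), conserved (0/1),
# label ('' = none), consensus (representative residue used by generators).
# Loop reference span: positions 33-38; matched with variable length.
index	region	allowed_residues	conserved	label	consensus
1	basic	*	0		A
2	basic	*	0		E
3	basic	*	0		R
4	basic	*	0		R
5	basic	*	0		R
6	basic	*	0		R
7	basic	*	0		M
8	basic	*	0		K
9	basic	HK	1	His/Lys-9	H
10	basic	*	0		L
11	basic	*	0		N
12	basic	*	0		N
13	basic	E	1	Glu-13	E
14	basic	R	1	Arg-14	R
15	basic	*	0	Gln-15	Q
16	basic	R	1	Arg-16	R
17	basic	R	1	Arg-17	R
18	helix1	*	0		G
19	helix1	*	0		E
20	helix1	ILV	1	Ile-20	I
21	helix1	N	1	Asn-21	N
22	helix1	*	0	Gln-22	Q
23	helix1	*	0		R
24	helix1	L	1	Leu-24	L
25	helix1	*	0		K
26	helix1	*	0		E
27	helix1	L	1	Leu-27	L
28	helix1	Q	1	Gln-28	Q
29	helix1	*	0		E
30	helix1	*	0		L
31	helix1	*	0	Val-31	V
32	helix1	*	0		P
33	loop	KRP	1	Lys-33	K
34	loop	*	0		G
35	loop	*	0		S
36	loop	*	0		K
37	loop	*	0		A
38	loop	*	0		D
39	helix2	KR	1	Lys-39	K
40	helix2	*	0		A
41	helix2	*	0		S
42	helix2	AS	1	Ala-42	A
43	helix2	ILV	1	Ile-43	I
44	helix2	*	0		L
45	helix2	*	0		D
46	helix2	ED	1	Glu-46	E
47	helix2	*	0		A
48	helix2	*	0		I
49	helix2	LIM	1	Leu-49	L
50	helix2	*	0		E
51	helix2	IV	1	Val-51	V
52	helix2	RK	1	Arg-52	R
53	helix2	*	0		A
54	helix2	L	1	Leu-54	L
55	helix2	*	0		Q
56	helix2	*	0		A
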