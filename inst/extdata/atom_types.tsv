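residue	atom	index	neighbor1	neighbor2
ALA	N	1	-C	CA
ALA	CA	2	N	C
ALA	C	3	CA	+N
ALA	O	4	C	CA
ALA	CB	5	CA	N
ARG	N	6	-C	CA
ARG	CA	7	N	C
ARG	C	8	CA	+N
ARG	O	9	C	CA
ARG	CB	10	CA	CG
ARG	CG	11	CB	CD
ARG	CD	12	CG	NE
ARG	NE	13	CD	CZ
ARG	CZ	14	NE	NH1
ARG	NH1	15	CZ	NE
ARG	NH2	16	CZ	NE
ASN	N	17	-C	CA
ASN	CA	18	N	C
ASN	C	19	CA	+N
ASN	O	20	C	CA
ASN	CB	21	CA	CG
ASN	CG	22	CB	OD1
ASN	OD1	23	CG	CB
ASN	ND2	24	CG	CB
ASP	N	25	-C	CA
ASP	CA	26	N	C
ASP	C	27	CA	+N
ASP	O	28	C	CA
ASP	CB	29	CA	CG
ASP	CG	30	CB	OD1
ASP	OD1	31	CG	CB
ASP	OD2	32	CG	CB
CYS	N	33	-C	CA
CYS	CA	34	N	C
CYS	C	35	CA	+N
CYS	O	36	C	CA
CYS	CB	37	CA	SG
CYS	SG	38	CB	CA
GLN	N	39	-C	CA
GLN	CA	40	N	C
GLN	C	41	CA	+N
GLN	O	42	C	CA
GLN	CB	43	CA	CG
GLN	CG	44	CB	CD
GLN	CD	45	CG	OE1
GLN	OE1	46	CD	CG
GLN	NE2	47	CD	CG
GLU	N	48	-C	CA
GLU	CA	49	N	C
GLU	C	50	CA	+N
GLU	O	51	C	CA
GLU	CB	52	CA	CG
GLU	CG	53	CB	CD
GLU	CD	54	CG	OE1
GLU	OE1	55	CD	CG
GLU	OE2	56	CD	CG
GLY	N	57	-C	CA
GLY	CA	58	N	C
GLY	C	59	CA	+N
GLY	O	60	C	CA
HIS	N	61	-C	CA
HIS	CA	62	N	C
HIS	C	63	CA	+N
HIS	O	64	C	CA
HIS	CB	65	CA	CG
HIS	CG	66	CB	ND1
HIS	ND1	67	CG	CE1
HIS	CD2	68	CG	NE2
HIS	CE1	69	ND1	NE2
HIS	NE2	70	CD2	CE1
ILE	N	71	-C	CA
ILE	CA	72	N	C
ILE	C	73	CA	+N
ILE	O	74	C	CA
ILE	CB	75	CA	CG1
ILE	CG1	76	CB	CD1
ILE	CG2	77	CB	CA
ILE	CD1	78	CG1	CB
LEU	N	79	-C	CA
LEU	CA	80	N	C
LEU	C	81	CA	+N
LEU	O	82	C	CA
LEU	CB	83	CA	CG
LEU	CG	84	CB	CD1
LEU	CD1	85	CG	CB
LEU	CD2	86	CG	CB
LYS	N	87	-C	CA
LYS	CA	88	N	C
LYS	C	89	CA	+N
LYS	O	90	C	CA
LYS	CB	91	CA	CG
LYS	CG	92	CB	CD
LYS	CD	93	CG	CE
LYS	CE	94	CD	NZ
LYS	NZ	95	CE	CD
MET	N	96	-C	CA
MET	CA	97	N	C
MET	C	98	CA	+N
MET	O	99	C	CA
MET	CB	100	CA	CG
MET	CG	101	CB	SD
MET	SD	102	CG	CE
MET	CE	103	SD	CG
PHE	N	104	-C	CA
PHE	CA	105	N	C
PHE	C	106	CA	+N
PHE	O	107	C	CA
PHE	CB	108	CA	CG
PHE	CG	109	CB	CD1
PHE	CD1	110	CG	CE1
PHE	CD2	111	CG	CE2
PHE	CE1	112	CD1	CZ
PHE	CE2	113	CD2	CZ
PHE	CZ	114	CE1	CE2
PRO	N	115	-C	CA
PRO	CA	116	N	C
PRO	C	117	CA	+N
PRO	O	118	C	CA
PRO	CB	119	CA	CG
PRO	CG	120	CB	CD
PRO	CD	121	CG	N
SER	N	122	-C	CA
SER	CA	123	N	C
SER	C	124	CA	+N
SER	O	125	C	CA
SER	CB	126	CA	OG
SER	OG	127	CB	CA
THR	N	128	-C	CA
THR	CA	129	N	C
THR	C	130	CA	+N
THR	O	131	C	CA
THR	CB	132	CA	OG1
THR	OG1	133	CB	CA
THR	CG2	134	CB	CA
TRP	N	135	-C	CA
TRP	CA	136	N	C
TRP	C	137	CA	+N
TRP	O	138	C	CA
TRP	CB	139	CA	CG
TRP	CG	140	CB	CD1
TRP	CD1	141	CG	NE1
TRP	CD2	142	CG	CE2
TRP	NE1	143	CD1	CE2
TRP	CE2	144	CD2	NE1
TRP	CE3	145	CD2	CZ3
TRP	CZ2	146	CE2	CH2
TRP	CZ3	147	CE3	CH2
TRP	CH2	148	CZ2	CZ3
TYR	N	149	-C	CA
TYR	CA	150	N	C
TYR	C	151	CA	+N
TYR	O	152	C	CA
TYR	CB	153	CA	CG
TYR	CG	154	CB	CD1
TYR	CD1	155	CG	CE1
TYR	CD2	156	CG	CE2
TYR	CE1	157	CD1	CZ
TYR	CE2	158	CD2	CZ
TYR	CZ	159	CE1	CE2
TYR	OH	160	CZ	CE1
VAL	N	161	-C	CA
VAL	CA	162	N	C
VAL	C	163	CA	+N
VAL	O	164	C	CA
VAL	CB	165	CA	CG1
VAL	CG1	166	CB	CA
VAL	CG2	167	CB	CA
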