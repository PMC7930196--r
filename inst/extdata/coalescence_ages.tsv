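event	soares_kyr	soares_lo	soares_hi	amtdna_kyr	amtdna_lo	amtdna_hi
MtEva	312	308	316	211	208	214
L3p4	150	142	158	102	96	108
L3	122	102	143	83	69	97
M	116	107	124	79	73	85
N	119	115	122	80	78	83
R	128	124	131	86	84	89
P	101	87	115	69	59	78
U5	63	57	70	43	39	47
A2	41	37	44	28	25	30
B2	46	37	55	31	25	37
C1	30	24	37	21	16	25
D1	32	17	47	22	12	32
D4h3a	26	22	29	17	15	21
X2a	22	14	31	15	10	21
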