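patient	sample	paired	role_sample	role_paired	total	shared	specific	cn_pct	set
P3	P3_P	P3_M1	primary	metastasis	216	212	4	44	matched
P3	P3_M1	P3_P	metastasis	primary	224	212	12	NA	matched
P3	P3_P	P3_M2	primary	metastasis	202	195	7	40	matched
P3	P3_M2	P3_P	metastasis	primary	212	195	17	NA	matched
P3	P3_M1	P3_M2	metastasis	metastasis	224	217	7	43	matched
P3	P3_M2	P3_M1	metastasis	metastasis	229	217	12	NA	matched
P6	P6_P	P6_M	primary	metastasis	163	162	1	42	matched
P6	P6_M	P6_P	metastasis	primary	165	162	3	NA	matched
P7	P7_P	P7_M	primary	metastasis	78	62	16	16	matched
P7	P7_M	P7_P	metastasis	primary	82	62	20	NA	matched
P8	P8_P	P8_M	primary	metastasis	52	36	16	25	matched
P8	P8_M	P8_P	metastasis	primary	59	36	23	NA	matched
P12	P12_P	P12_M1	primary	metastasis	38	29	9	28	matched
P12	P12_M1	P12_P	metastasis	primary	43	29	14	NA	matched
P12	P12_P	P12_M2	primary	metastasis	40	30	10	29	matched
P12	P12_M2	P12_P	metastasis	primary	39	30	9	NA	matched
P12	P12_M1	P12_M2	metastasis	metastasis	38	35	3	36	matched
P12	P12_M2	P12_M1	metastasis	metastasis	39	35	4	NA	matched
P14	P14_P	P14_M	primary	metastasis	54	50	4	33	matched
P14	P14_M	P14_P	metastasis	primary	56	50	6	NA	matched
P15	P15_P	P15_M	primary	metastasis	26	16	10	27	matched
P15	P15_M	P15_P	metastasis	primary	18	16	2	NA	matched
P16	P16_P	P16_M	primary	metastasis	100	99	1	24	matched
P16	P16_M	P16_P	metastasis	primary	117	99	18	NA	matched
P17	P17_P	P17_M	primary	metastasis	82	82	0	40	matched
P17	P17_M	P17_P	metastasis	primary	87	82	5	NA	matched
P18	P18_P	P18_M	primary	metastasis	310	269	41	35	matched
P18	P18_M	P18_P	metastasis	primary	404	269	135	NA	matched
P20	P20_P	P20_M	primary	metastasis	212	174	38	36	matched
P20	P20_M	P20_P	metastasis	primary	221	174	47	NA	matched
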