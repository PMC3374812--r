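gene_id	chrom	start	end	cytoband	hazard_ratio	p_value
STARD3	chr17	35,046,940	35,073,248	17q12	2.23	4.19E-03
ERBB2	chr17	35,110,005	35,122,109	17q12	1.91	2.16E-02
GRB7	chr17	35,152,029	35,156,782	17q12	1.83	5.12E-02
GSDML	chr17	35,326,079	35,328,194	17q12	2.51	1.72E-03
PSMD3	chr17	35,390,607	35,407,732	17q12	1.78	3.57E-02
PHB	chr17	44,836,413	44,847,246	17q21.33	2.48	7.96E-04
SLC35B1	chr17	45,133,688	45,140,281	17q21.33	1.81	3.87E-02
SUPT4H1	chr17	53,778,283	53,784,556	17q22	2.20	5.11E-03
RAD51C	chr17	54,124,987	54,127,694	17q22	1.83	3.53E-02
CLTC	chr17	55,052,102	55,126,906	17q23.1	2.04	8.80E-03
PTRH2	chr17	55,129,449	55,139,638	17q23.1	1.96	1.27E-02
ABC1	chr17	55,475,337	55,499,876	17q23.1	2.15	1.36E-02
APPBP2	chr17	55,875,300	55,958,365	17q23.2	1.84	3.40E-02
TRIM37	chr17	57,059,999	57,184,266	17q23.2	1.84	3.39E-02
USP32	chr17	58,254,691	58,469,586	17q23.2	2.17	7.02E-03
CYB561	chr17	58,864,245	58,869,052	17q23.3	2.22	5.45E-03
CCDC44	chr17	59,038,377	59,039,456	17q23.3	1.89	3.97E-02
PSMC5	chr17	59,258,832	59,263,111	17q23.3	2.19	5.37E-03
PSMD12	chr17	62,764,494	62,793,171	17q24.2	1.98	1.94E-02
KPNA2	chr17	66,031,848	66,042,970	17q24.2	1.76	4.87E-02
ICT1	chr17	70,520,374	70,528,950	17q25.1	2.33	3.23E-03
ATP5H	chr17	70,546,552	70,548,888	17q25.1	1.91	3.55E-02
MRPS7	chr17	70,769,394	70,773,734	17q25.1	1.82	3.31E-02
SAP30BP	chr17	71,175,038	71,214,431	17q25.1	1.81	4.18E-02
SPFH2	chr8	37,713,267	37,734,476	8p11.2	1.85	2.55E-02
PROSC	chr8	37,739,282	37,756,441	8p11.2	2.19	6.19E-03
ASH2L	chr8	38,082,214	38,116,216	8p11.2	2.12	7.31E-03
LSM1	chr8	38,140,017	38,153,183	8p11.2	2.39	1.08E-03
WHSC1L1	chr8	38,293,091	38,358,947	8p11.2	2.28	3.90E-03
BRF2	chr8	37,821,053	37,826,512	8p12	3.04	2.62E-05
DDHD2	chr8	38,208,356	38,239,442	8p12	2.15	6.66E-03
UBE2V2	chr8	49,083,545	49,136,681	8q11.21	2.11	9.08E-03
ATP6V1H	chr8	54,828,192	54,832,484	8q11.23	2.45	1.47E-03
MRPL15	chr8	55,210,341	55,223,011	8q11.23	2.27	3.53E-03
COPS5	chr8	68,117,869	68,136,905	8q13.2	1.82	2.45E-02
TCEB1	chr8	75,020,403	75,047,049	8q21.11	2.74	3.53E-04
FAM82B	chr8	87,555,453	87,590,037	8q21.3	2.01	1.46E-02
UQCRB	chr8	97,312,308	97,316,963	8q22	2.13	8.20E-03
POLR2K	chr8	101,232,001	101,235,407	8q22.2	1.74	5.18E-02
ATP6V1C1	chr8	104,102,463	104,152,473	8q22.3	1.81	4.87E-02
EBAG9	chr8	110,621,485	110,646,565	8q23	1.80	4.48E-02
YWHAZ	chr8	102,001,097	102,033,426	8q23.1	2.85	1.30E-03
ENY2	chr8	110,415,745	110,425,074	8q23.1	2.70	3.08E-04
RAD21	chr8	117,927,353	117,956,221	8q24	1.95	2.60E-02
SQLE	chr8	126,100,439	126,102,952	8q24.1	2.13	1.49E-02
MRPL13	chr8	121,477,267	121,526,557	8q24.12	2.93	1.90E-04
SCRIB	chr8	144,945,082	144,968,239	8q24.3	2.39	5.07E-03
SIAHBP1	chr8	144,970,536	144,983,471	8q24.3	1.97	1.59E-02
GRINA	chr8	145,136,247	145,139,570	8q24.3	2.07	1.12E-02
EXOSC4	chr8	145,205,516	145,207,538	8q24.3	2.14	7.84E-03
CYC1	chr8	145,221,982	145,224,415	8q24.3	2.45	4.97E-03
SHARPIN	chr8	145,225,527	145,230,852	8q24.3	2.12	1.84E-02
C8orf30A	chr8	145,264,659	145,267,608	8q24.3	1.80	4.97E-02
BOP1	chr8	145,456,867	145,485,928	8q24.3	2.30	5.71E-03
HSF1	chr8	145,497,218	145,498,193	8q24.3	2.36	1.24E-02
FBXL6	chr8	145,549,899	145,552,940	8q24.3	2.62	6.13E-04
GPR172A	chr8	145,553,131	145,555,738	8q24.3	2.99	2.81E-04
VPS28	chr8	145,619,807	145,623,174	8q24.3	2.34	2.53E-03
RPL8	chr8	145,985,957	145,988,332	8q24.3	2.18	6.48E-03
ZNF7	chr8	146,023,747	146,043,697	8q24.3	2.17	8.43E-03
ZNF250	chr8	146,076,967	146,079,026	8q24.3	1.83	3.51E-02
C8orf33	chr8	146,248,629	146,251,814	8q24.3	1.94	1.63E-02
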