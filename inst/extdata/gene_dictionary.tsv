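symbol	gene_id	aliases
MGMT	4255	AGT|MGMT1
BRCA1	672	BRCAI|RNF53
BRCA2	675	FANCD1
GSTP1	2950	GST3|PI
ESR1	2099	ER|ESR
ESR2	2100	ERB
CDKN2A	1029	p16|INK4A|p16INK4a|MTS1
CDKN2B	1030	p15|INK4B
MLH1	4292	HNPCC|HNPCC2
DAPK1	1612	DAPK
CDH1	999	ECAD|UVO
CDH13	1013	CDHH
TIMP3	7078	SFD
TP73	7161	P73
TP53	7157	p53|LFS1
APC	324	DP2.5
SOCS1	8651	JAB|SSI1
SOCS2	8835	CIS2|SSI2
SOCS3	9021	CIS3|SSI3
RASSF1	11186	RASSF1A|RDA32
RASSF5	83593	NORE1
RARB	5915	RRB2
PYCARD	29108	ASC|TMS1
COX2	4513	MTCO2
PTGS2	5743	COX-2|PGHS2
GATA4	2626	GATA-4
SYK	6850	p72Syk
PRDM2	7799	RIZ|RIZ1
PGR	5241	PR|NR3C3
SFRP1	6422	FRP1|SARP2
STK11	6794	LKB1|PJS
TMEFF2	23671	TPEF|HPP1
THBS1	7057	TSP1
PRKCDBP	112464	SRBC
VHL	7428	RCA1
RB1	5925	RB|OSRC
MYOD1	4654	MYOD
CALCA	796	CT
HIC1	3090	ZBTB29
CCND2	894	KIAK0002
DNMT1	1786	DNMT|MCMT
MECP2	4204	RTT
MIR9-1	407046	miR-9-1|hsa-mir-9-1
MIR34A	407040	miR-34a
MIR181C	406957	miR-181c
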