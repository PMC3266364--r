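acronym	expansion
NPC	nasopharyngeal carcinoma
CRC	colorectal cancer
HCC	hepatocellular carcinoma
RCC	renal cell carcinoma
SCC	squamous cell carcinoma
AML	acute myeloid leukemia
ALL	acute lymphoblastic leukemia
CML	chronic myeloid leukemia
CLL	chronic lymphocytic leukemia
NSCLC	non-small cell lung cancer
SCLC	small cell lung cancer
GBM	glioblastoma multiforme
DLBCL	diffuse large b-cell lymphoma
MM	multiple myeloma
HNSCC	head and neck squamous cell carcinoma
ESCC	esophageal squamous cell carcinoma
DCIS	ductal carcinoma in situ
TCC	transitional cell carcinoma
MDS	myelodysplastic syndrome
GIST	gastrointestinal stromal tumor
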