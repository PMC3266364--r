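name
nasopharyngeal carcinoma
hepatocellular carcinoma
renal cell carcinoma
squamous cell carcinoma
acute myeloid leukemia
acute lymphoblastic leukemia
chronic myeloid leukemia
chronic lymphocytic leukemia
non-small cell lung cancer
small cell lung cancer
malignant melanoma
multiple myeloma
hodgkin lymphoma
non-hodgkin lymphoma
diffuse large b-cell lymphoma
glioblastoma multiforme
colorectal adenocarcinoma
gastric adenocarcinoma
ductal carcinoma in situ
transitional cell carcinoma
medullary thyroid carcinoma
papillary thyroid carcinoma
cervical intraepithelial neoplasia
malignant mesothelioma
ewing sarcoma
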