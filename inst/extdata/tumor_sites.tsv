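site
breast
lung
colorectal
colon
rectal
gastric
stomach
liver
hepatic
esophageal
oesophageal
bladder
blood
kidney
renal
ovarian
pancreatic
endometrial
lymphatic
prostate
cervical
brain
skin
oral
head
neck
thyroid
testicular
bone
gallbladder
laryngeal
nasopharyngeal
uterine
vulvar
adrenal
pituitary
salivary
intestinal
duodenal
anal
pleural
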