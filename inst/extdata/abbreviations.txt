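# Abbreviations whose trailing period does not end a sentence.
et al.
al.
Fig.
Figs.
vs.
e.g.
i.e.
cf.
approx.
ca.
No.
Dr.
Prof.
St.
resp.
spp.
subsp.
var.
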