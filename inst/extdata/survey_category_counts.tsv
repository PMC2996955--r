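category	cdna	genes
5UTR	20	19
5UTR_CDS	143	134
CDS	142	137
CDS_3UTR	549	499
3UTR	532	443
5UTR_CDS_3UTR	204	181
NR_XR	58	49
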