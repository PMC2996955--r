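category	n	mean_pct
5UTR_CDS	14	95.1
5UTR_CDS_3UTR	42	95.9
CDS	19	96.8
CDS_3UTR	104	95.7
3UTR	119	93.3
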