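region	transcripts
5UTR	14
5UTR_CDS	7
CDS	70
CDS_3UTR	11
3UTR	98
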