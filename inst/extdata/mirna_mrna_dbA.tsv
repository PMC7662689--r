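mirna	target
hsa-miR-21-5p	PTEN
hsa-miR-21-5p	PDCD4
hsa-miR-155-5p	SOCS1
hsa-miR-17-5p	VEGFA
hsa-let-7a-5p	HMGA2
hsa-miR-21-5p	PTEN
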