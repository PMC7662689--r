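mirna	target
hsa-miR-21-5p	NEAT1
hsa-miR-155-5p	NEAT1
hsa-miR-21-5p	HOTAIR
hsa-miR-17-5p	HOTAIR
hsa-let-7a-5p	H19
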