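snp	gene	mediator	outcome	ade	acme
rs11208712	Intergenic	CRP	BMI	-0.12	0.25
rs439401	APOE	WHR	CRP	0.64	0.05
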