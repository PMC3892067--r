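strain_gene	mode	model_target	partner
clb1	lumped-pair	CLB1_CLB2	clb2
clb2	lumped-pair	CLB1_CLB2	clb1
clb5	lumped-pair	CLB5_CLB6	clb6
clb6	lumped-pair	CLB5_CLB6	clb5
cln1	lumped-pair	CLN1_CLN2	cln2
cln2	lumped-pair	CLN1_CLN2	cln1
cln3	lumped-pair	CLN3_BCK2	bck2
bck2	lumped-pair	CLN3_BCK2	cln3
swi6	complex-component	act_SBF,act_MBF	
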