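strain	vector_mean	vector_sd	tev_mean	tev_sd	n
Wild type	149.7	43.4	59.8	19.9	4
bck2	44.3	3.4	25.3	0.8	4
bub2	71.4	8.4	48.6	3.5	4
cdh1	66.7	5.7	19.6	2.2	4
cin8	53.7	20.0	37.1	5.0	4
clb1	57.6	5.2	19.2	2.2	4
clb2	56.3	4.3	20.2	7.8	4
clb3	77.5	15.1	27.7	3.6	4
clb4	59.4	4.5	19.3	2.1	4
clb5	98.0	21.4	33.6	6.5	4
clb6	76.1	8.6	31.6	2.7	4
cln1	80.1	24.3	20.7	0.6	4
cln2	82.7	15.8	42.9	3.8	4
cln3	47.0	10.9	22.0	10.8	4
lte1	84.8	20.9	32.0	16.0	4
mad2	47.4	6.0	35.2	2.9	4
mbp1	21.6	11.4	15.0	2.1	4
mih1	64.4	12.1	29.3	3.7	4
sic1	71.8	20.1	20.2	11.8	4
swe1	124.4	13.0	42.2	5.3	4
swi4	76.1	15.1	28.4	6.6	4
swi5	94.0	23.8	37.3	12.6	4
swi6	64.0	8.7	35.2	7.2	4
whi5	69.6	15.8	33.8	10.9	4
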