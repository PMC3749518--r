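tree	mollicutes_erysipelotrichia	actinobacteria	bacteroidetes	cyanobacteria	alphaproteobacteria	beta_gamma_proteobacteria	delta_epsilon_proteobacteria	spirochaetes	published_sum
Ala	1	3	1	1	1	1	5	2	14
Arg	3	6	2	2	2	5	12	3	32
Asn	1	1	2	1	NA	1	7	2	14
Asp	6	8	3	1	1	2	5	3	23
Cys	1	2	2	1	6	5	7	4	27
Glu	2	5	1	2	3	3	10	2	26
His	1	10	2	3	3	3	10	3	34
Ile	1	3	1	1	3	2	9	2	21
Leu	6	5	3	1	4	1	11	3	28
Lys	1	3	1	1	NA	1	6	1	13
Met	5	7	1	2	10	3	8	3	34
Phe	1	2	1	1	1	1	6	3	15
Pro	2	8	2	1	2	2	9	3	27
Ser	6	7	3	1	1	1	11	3	27
Thr	4	7	1	4	3	10	8	3	36
Trp	3	6	8	1	2	12	14	9	52
Tyr	3	5	2	1	2	3	12	4	29
Val	1	5	2	1	2	1	8	2	21
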