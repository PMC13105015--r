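tool	variant_type	direction	prior	level	threshold	interval_low	interval_high	low_inclusive	high_inclusive	support_n	excluded_reason
CADD	deletion	higher_pathogenic	0.046	-3	0.878	-Inf	0.878	FALSE	TRUE	NA	NA
CADD	deletion	higher_pathogenic	0.046	-2	9.81	0.878	9.81	FALSE	TRUE	NA	NA
CADD	deletion	higher_pathogenic	0.046	-1	14.91	9.81	14.91	FALSE	TRUE	NA	NA
CADD	deletion	higher_pathogenic	0.046	1	21.9	21.9	Inf	TRUE	FALSE	NA	NA
FATHMM-indel	deletion	higher_pathogenic	0.046	-4	0.048	-Inf	0.048	FALSE	TRUE	NA	NA
FATHMM-indel	deletion	higher_pathogenic	0.046	-3	0.127	0.048	0.127	FALSE	TRUE	NA	NA
FATHMM-indel	deletion	higher_pathogenic	0.046	-2	0.365	0.127	0.365	FALSE	TRUE	NA	NA
FATHMM-indel	deletion	higher_pathogenic	0.046	-1	0.675	0.365	0.675	FALSE	TRUE	NA	NA
FATHMM-indel	deletion	higher_pathogenic	0.046	1	0.961	0.961	0.982	TRUE	FALSE	NA	NA
FATHMM-indel	deletion	higher_pathogenic	0.046	2	0.982	0.982	Inf	TRUE	FALSE	NA	NA
INDELpred	deletion	higher_pathogenic	0.046	-4	0.023	-Inf	0.023	FALSE	TRUE	NA	NA
INDELpred	deletion	higher_pathogenic	0.046	-3	0.037	0.023	0.037	FALSE	TRUE	NA	NA
INDELpred	deletion	higher_pathogenic	0.046	-2	0.090	0.037	0.090	FALSE	TRUE	NA	NA
INDELpred	deletion	higher_pathogenic	0.046	-1	0.153	0.090	0.153	FALSE	TRUE	NA	NA
INDELpred	deletion	higher_pathogenic	0.046	1	0.781	0.781	Inf	TRUE	FALSE	NA	NA
MutPred-Indel	deletion	higher_pathogenic	0.046	-2	0.165	-Inf	0.165	FALSE	TRUE	NA	NA
MutPred-Indel	deletion	higher_pathogenic	0.046	-1	0.221	0.165	0.221	FALSE	TRUE	NA	NA
MutPred-Indel	deletion	higher_pathogenic	0.046	1	0.659	0.659	0.779	TRUE	FALSE	NA	NA
MutPred-Indel	deletion	higher_pathogenic	0.046	2	0.779	0.779	0.834	TRUE	FALSE	NA	NA
MutPred-Indel	deletion	higher_pathogenic	0.046	3	0.834	0.834	Inf	TRUE	FALSE	NA	NA
VEST-Indel	deletion	higher_pathogenic	0.046	-3	0.16	-Inf	0.16	FALSE	TRUE	NA	NA
VEST-Indel	deletion	higher_pathogenic	0.046	-2	0.35	0.16	0.35	FALSE	TRUE	NA	NA
VEST-Indel	deletion	higher_pathogenic	0.046	-1	0.40	0.35	0.40	FALSE	TRUE	NA	NA
VEST-Indel	deletion	higher_pathogenic	0.046	1	0.83	0.83	0.92	TRUE	FALSE	NA	NA
VEST-Indel	deletion	higher_pathogenic	0.046	2	0.92	0.92	0.98	TRUE	FALSE	NA	NA
VEST-Indel	deletion	higher_pathogenic	0.046	3	0.98	0.98	Inf	TRUE	FALSE	NA	NA
ESM1b	deletion	lower_pathogenic	0.046	1	-3.45	-8.55	-3.45	FALSE	TRUE	NA	NA
ESM1b	deletion	lower_pathogenic	0.046	2	-8.55	-12.79	-8.55	FALSE	TRUE	NA	NA
ESM1b	deletion	lower_pathogenic	0.046	3	-12.79	-Inf	-12.79	FALSE	TRUE	NA	NA
ProGen2	deletion	lower_pathogenic	0.046	-1	0.0	0.0	Inf	TRUE	FALSE	NA	NA
ProGen2	deletion	lower_pathogenic	0.046	1	-0.030	-0.052	-0.030	FALSE	TRUE	NA	NA
ProGen2	deletion	lower_pathogenic	0.046	2	-0.052	-0.129	-0.052	FALSE	TRUE	NA	NA
ProGen2	deletion	lower_pathogenic	0.046	3	-0.129	-Inf	-0.129	FALSE	TRUE	NA	NA
PROVEAN	deletion	lower_pathogenic	0.046	-4	-0.28	-0.28	Inf	TRUE	FALSE	NA	NA
PROVEAN	deletion	lower_pathogenic	0.046	-3	-0.53	-0.53	-0.28	TRUE	FALSE	NA	NA
PROVEAN	deletion	lower_pathogenic	0.046	-2	-2.29	-2.29	-0.53	TRUE	FALSE	NA	NA
PROVEAN	deletion	lower_pathogenic	0.046	-1	-4.80	-4.80	-2.29	TRUE	FALSE	NA	NA
PROVEAN	deletion	lower_pathogenic	0.046	1	-9.10	-19.82	-9.10	FALSE	TRUE	NA	NA
PROVEAN	deletion	lower_pathogenic	0.046	2	-19.82	-23.07	-19.82	FALSE	TRUE	NA	NA
PROVEAN	deletion	lower_pathogenic	0.046	3	-23.07	-Inf	-23.07	FALSE	TRUE	NA	NA
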