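tool	variant_type	direction	prior	level	threshold	interval_low	interval_high	low_inclusive	high_inclusive	support_n	excluded_reason
CADD	insertion	higher_pathogenic	0.008	-1	4.72	-Inf	4.72	FALSE	TRUE	NA	NA
CADD	insertion	higher_pathogenic	0.008	1	20.3	20.3	34.0	TRUE	FALSE	NA	NA
CADD	insertion	higher_pathogenic	0.008	2	34.0	34.0	Inf	TRUE	FALSE	NA	NA
FATHMM-indel	insertion	higher_pathogenic	0.008	-1	0.008	-Inf	0.008	FALSE	TRUE	NA	NA
FATHMM-indel	insertion	higher_pathogenic	0.008	1	0.845	0.845	Inf	TRUE	FALSE	NA	NA
INDELpred	insertion	higher_pathogenic	0.008	-4	0.008	-Inf	0.008	FALSE	TRUE	NA	NA
INDELpred	insertion	higher_pathogenic	0.008	-3	0.010	0.008	0.010	FALSE	TRUE	NA	NA
INDELpred	insertion	higher_pathogenic	0.008	-2	0.054	0.010	0.054	FALSE	TRUE	NA	NA
INDELpred	insertion	higher_pathogenic	0.008	-1	0.127	0.054	0.127	FALSE	TRUE	NA	NA
MutPred-Indel	insertion	higher_pathogenic	0.008	-1	0.212	-Inf	0.212	FALSE	TRUE	NA	NA
MutPred-Indel	insertion	higher_pathogenic	0.008	1	0.691	0.691	0.838	TRUE	FALSE	NA	NA
MutPred-Indel	insertion	higher_pathogenic	0.008	2	0.838	0.838	Inf	TRUE	FALSE	NA	NA
VEST-Indel	insertion	higher_pathogenic	0.008	-1	0.21	-Inf	0.21	FALSE	TRUE	NA	NA
VEST-Indel	insertion	higher_pathogenic	0.008	1	0.80	0.80	0.91	TRUE	FALSE	NA	NA
VEST-Indel	insertion	higher_pathogenic	0.008	2	0.91	0.91	1.0	TRUE	FALSE	NA	NA
VEST-Indel	insertion	higher_pathogenic	0.008	3	1.0	1.0	Inf	TRUE	FALSE	NA	NA
ESM1b	insertion	lower_pathogenic	0.008	1	-4.25	-7.52	-4.25	FALSE	TRUE	NA	NA
ESM1b	insertion	lower_pathogenic	0.008	2	-7.52	-Inf	-7.52	FALSE	TRUE	NA	NA
ProGen2	insertion	lower_pathogenic	0.008	1	-0.037	-0.076	-0.037	FALSE	TRUE	NA	NA
ProGen2	insertion	lower_pathogenic	0.008	2	-0.076	-Inf	-0.076	FALSE	FALSE	NA	NA
PROVEAN	insertion	lower_pathogenic	0.008	-2	0.64	0.64	Inf	TRUE	FALSE	NA	NA
PROVEAN	insertion	lower_pathogenic	0.008	-1	-1.19	-1.19	0.64	TRUE	FALSE	NA	NA
PROVEAN	insertion	lower_pathogenic	0.008	1	-6.69	-8.17	-6.69	FALSE	TRUE	NA	NA
PROVEAN	insertion	lower_pathogenic	0.008	2	-8.17	-Inf	-8.17	FALSE	TRUE	NA	NA
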