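# Sectored-colony counts (sectored red/white colonies / total colonies screened)
# for UV-irradiated and unirradiated W303-1A x YJM789 hybrid diploids, with the
# selected SUP4-o marker on chromosome V or IV. Rows without raw counts carry
# the published frequency in `freq`. `baseline` / `alt_baseline` point at the
# comparison row for fold increases.
id	strain	genotype	sup4_chrom	uv_dose	sectored	total	freq	baseline	alt_baseline
PG311_V_0	PG311	WT	V	0	NA	NA	1.1e-6	NA	NA
PG311_V_1	PG311	WT	V	1	47	45544	NA	PG311_V_0	NA
PG311_V_15	PG311	WT	V	15	36	7194	NA	PG311_V_0	NA
JSC25_IV_0	JSC25	WT	IV	0	55	1761664	NA	NA	NA
JSC25_IV_1	JSC25	WT	IV	1	18	2564	NA	JSC25_IV_0	NA
JSC25_IV_15	JSC25	WT	IV	15	110	1420	NA	JSC25_IV_0	NA
rad14_V_0	YYy23.4	rad14	V	0	0	22797	NA	NA	NA
rad14_V_1	YYy23.4	rad14	V	1	23	4853	NA	NA	NA
rad14_IV_0	YYy37.6	rad14	IV	0	20	144771	NA	NA	NA
rad14_IV_1	YYy37.6	rad14	IV	1	99	3216	NA	rad14_IV_0	JSC25_IV_0
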