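# Single-chromatid-break (SCB) vs double-sister-chromatid-break (DSCB) event
# counts, split into selected (crossover on the marked chromosome V arm) and
# unselected events. total_* re-enter the published totals, which for the
# WT_15 row exceed the selected+unselected sum.
id	strain	genotype	uv_dose	sel_scb	sel_dscb	unsel_scb	unsel_dscb	total_scb	total_dscb
WT_1	PG311	WT	1	31	10	NA	NA	31	10
WT_15	PG311	WT	15	5	12	76	106	92	118
rad14_1	YYy23.4	rad14	1	7	2	58	18	65	20
mus81_15	YYy76.14	mus81	15	2	5	27	38	29	43
yen1_15	YYy71.28	yen1	15	2	10	46	48	48	58
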