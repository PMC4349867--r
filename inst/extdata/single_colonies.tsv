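# Unselected LOH events scored in single colonies (strains too UV-sensitive
# for the sectored-colony assay), 1 J/m2: interstitial events, pooled
# crossover+BIR terminal events, totals, colonies analyzed.
id	genotype	interstitial	co_bir	total	colonies	interstitial_indels	terminal_indels	ploidy
rad14	rad14	46	26	72	21	2	2	1
rad14_mus81	rad14 mus81	13	17	30	24	3	1	0
rad14_yen1	rad14 yen1	30	22	52	18	3	0	1
rad14_mms2	rad14 mms2	61	55	116	21	4	0	3
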