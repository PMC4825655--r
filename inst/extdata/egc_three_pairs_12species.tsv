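# Empirical genome coverage (EgC, %) of 12 plant species for three enzyme
# pairs from a published MiSeq GBS survey: PM = PstI+MspI (reference),
# AB = AvaII+BfaI, HH = HinfI+HpyCH4IV. The ratio columns are the published
# per-species EgC ratios relative to PM (computed there from full-precision
# coverages, hence not exactly the quotient of the rounded EgC columns).
species	group	pm_egc	ab_egc	ab_ratio	hh_egc	hh_ratio
Arabidopsis_thaliana	dicot	0.74	2.28	3.09	4.45	6.03
Pisum_sativum	dicot	0.10	0.95	9.35	0.55	5.45
Linum_grandiflorum	dicot	1.36	2.55	1.87	4.37	3.21
Carthamus_tinctorius	dicot	0.32	1.83	5.67	1.72	5.34
Glycine_max	dicot	0.71	3.33	4.67	3.33	4.67
Sinapis_alba	dicot	1.54	4.83	3.13	6.41	4.16
Aegilops_umbellulata	monocot	0.43	0.75	1.76	0.93	2.19
Pseudoroegneria_spicata	monocot	0.67	1.35	2.02	1.24	1.85
Agropyron_cristatum	monocot	0.56	1.00	1.78	0.92	1.65
Zea_mays	monocot	0.58	1.51	2.62	1.62	2.81
Elymus_lanceolatus	monocot	0.52	0.59	1.12	0.73	1.39
Oryza_sativa	monocot	3.02	6.36	2.11	7.90	2.61
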