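rate	ci_low	ci_high	source
1.67	1.37	1.97	modern_phylogenetic
1.91	1.72	2.10	study_oldest_period
1.92	1.16	2.68	ancient_tip_dated_a
2.23	1.71	2.75	ancient_tip_dated_b
2.40	1.70	3.20	ancient_tip_dated_c
2.53	1.80	3.20	ancient_tip_dated_d
2.67	2.16	3.16	ancient_tip_dated_e
2.74	2.44	3.01	ancient_tip_dated_f
4.33	3.90	4.82	study_youngest_period
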