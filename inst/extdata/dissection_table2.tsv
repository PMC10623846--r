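sample	tert_mutation	area	micro_cellularity	tert_vaf	mgmt_level_pct
1	c.-124C>T	high	60	0.311	52.213
1	c.-124C>T	low	10	0.152	18.800
2	c.-124C>T	high	80	0.214	30.332
2	c.-124C>T	low	20	0.077	4.553
3	c.-124C>T	high	80	0.376	59.323
3	c.-124C>T	low	5	0.056	11.865
4	c.-124C>T	high	60	0.386	67.633
4	c.-124C>T	low	40	0.440	75.486
5	c.-124C>T	high	90	0.315	68.293
5	c.-124C>T	low	50	0.263	57.687
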