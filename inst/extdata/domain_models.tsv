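gene	domain	aa_start	aa_end
JAK1	FERM	34	420
JAK1	SH2	439	544
JAK1	SH2-JH2 linker	545	582
JAK1	JH2	583	855
JAK1	JH1	875	1153
JAK3	FERM	24	356
JAK3	SH2	372	459
JAK3	SH2-JH2 linker	460	520
JAK3	JH2	521	781
JAK3	JH1	822	1078
TYK2	FERM	26	431
TYK2	SH2	450	529
TYK2	SH2-JH2 linker	530	588
TYK2	JH2	589	875
TYK2	JH1	897	1176
STAT4	coiled-coil	138	330
STAT4	DNA-binding	331	496
STAT4	SH2	573	657
STAT4	transactivation	722	748
STAT5A	coiled-coil	138	330
STAT5A	DNA-binding	331	496
STAT5A	SH2	593	685
STAT5A	transactivation	722	794
STAT5B	coiled-coil	138	330
STAT5B	DNA-binding	331	496
STAT5B	SH2	593	685
STAT5B	transactivation	722	787
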