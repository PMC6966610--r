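gene	exon	aa_start	aa_end
JAK1	1	1	30
JAK1	2	31	90
JAK1	3	91	150
JAK1	4	151	210
JAK1	5	211	270
JAK1	6	271	330
JAK1	7	331	390
JAK1	8	391	440
JAK1	9	441	480
JAK1	10	481	510
JAK1	11	511	530
JAK1	12	531	545
JAK1	13	546	560
JAK1	14	561	600
JAK1	15	601	640
JAK1	16	641	670
JAK1	17	671	710
JAK1	18	711	750
JAK1	19	751	839
JAK1	20	840	880
JAK1	21	881	940
JAK1	22	941	1000
JAK1	23	1001	1060
JAK1	24	1061	1110
JAK1	25	1111	1154
JAK3	1	1	27
JAK3	2	28	80
JAK3	3	81	140
JAK3	4	141	200
JAK3	5	201	260
JAK3	6	261	320
JAK3	7	321	375
JAK3	8	376	430
JAK3	9	431	470
JAK3	10	471	500
JAK3	11	501	545
JAK3	12	546	570
JAK3	13	571	600
JAK3	14	601	630
JAK3	15	631	660
JAK3	16	661	690
JAK3	17	691	720
JAK3	18	721	755
JAK3	19	756	790
JAK3	20	791	830
JAK3	21	831	900
JAK3	22	901	970
JAK3	23	971	1045
JAK3	24	1046	1124
STAT5B	1	1	20
STAT5B	2	21	70
STAT5B	3	71	120
STAT5B	4	121	170
STAT5B	5	171	220
STAT5B	6	221	270
STAT5B	7	271	320
STAT5B	8	321	370
STAT5B	9	371	410
STAT5B	10	411	450
STAT5B	11	451	490
STAT5B	12	491	530
STAT5B	13	531	565
STAT5B	14	566	599
STAT5B	15	600	645
STAT5B	16	646	680
STAT5B	17	681	712
STAT5B	18	713	750
STAT5B	19	751	787
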