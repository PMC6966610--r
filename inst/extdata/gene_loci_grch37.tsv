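symbol	alias	chrom	start	end	strand
JAK1	JAK1	1	65298906	65432187	-
JAK2	JAK2	9	4985033	5128183	+
JAK3	JAK3	19	17935589	17958880	-
TYK2	TYK2	19	10461204	10491352	-
STAT1	STAT1	2	191829084	191885686	-
STAT2	STAT2	12	56735381	56754037	-
STAT3	STAT3	17	40465342	40540405	-
STAT4	STAT4	2	191894302	192015925	-
STAT5A	STAT5A	17	40439565	40463961	+
STAT5B	STAT5B	17	40351195	40428424	-
STAT6	STAT6	12	57489187	57505196	-
DUSP4	DUSP4	8	29192774	29210411	-
PTPRC	CD45	1	198608098	198726605	+
PTPN2	TCPTP	18	12785478	12884337	-
PTPN6	SHP1	12	7055740	7070479	+
SOCS1	SOCS1	16	11348274	11350039	-
SOCS3	SOCS3	17	76352859	76356158	-
HDAC9	HDAC9	7	18126572	19036992	+
TCL1A	TCL1A	14	96176565	96180536	-
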