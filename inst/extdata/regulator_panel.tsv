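gene	alias	direction
DUSP4	DUSP4	loss_activating
PTPRC	CD45	loss_activating
PTPN2	TCPTP	loss_activating
PTPN6	SHP1	loss_activating
SOCS1	SOCS1	loss_activating
SOCS3	SOCS3	loss_activating
HDAC9	HDAC9	loss_activating
STAT2	STAT2	gain_activating
STAT3	STAT3	gain_activating
STAT5A	STAT5A	gain_activating
STAT5B	STAT5B	gain_activating
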