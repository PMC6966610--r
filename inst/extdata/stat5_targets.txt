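CISH
PIM1
OSM
BCL2L1
MYC
SOCS2
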