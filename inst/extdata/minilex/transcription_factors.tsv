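# Transcription factors (regulatory genes, kept distinct from structural genes).
ZEB1	ZEB1
ZEB2	ZEB2
SP1	SP1
TWIST1	TWIST1
SNAI1	SNAI1
GATA6	GATA6
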