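# Target genes, HGNC-style symbols plus common mixed-case spellings.
SMAD7	SMAD7
Smad7	SMAD7
SMAD3	SMAD3
Smad3	SMAD3
COL1A2	COL1A2
COL1A1	COL1A1
COL3A1	COL3A1
SERPINE1	SERPINE1
ACTA2	ACTA2
CDH1	CDH1
TGFB1	TGFB1
CTGF	CTGF
MMP7	MMP7
THY1	THY1
FOXO3	FOXO3
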