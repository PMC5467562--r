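term	polarity
increase	positive
increased	positive
increases	positive
induced	positive
induction	positive
upregulated	positive
up-regulated	positive
overexpressed	positive
overexpression	positive
elevated	positive
higher	positive
up	positive
decrease	negative
decreased	negative
decreases	negative
repressed	negative
repression	negative
downregulated	negative
down-regulated	negative
reduced	negative
diminished	negative
suppressed	negative
inhibited	negative
deleted	negative
lower	negative
down	negative
constant	none
unchanged	none
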