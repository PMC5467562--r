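# Regulatory-effect vocabulary (level changes of a miRNA or its target).
increase
increased
increases
decrease
decreased
decreases
induced
induction
repressed
repression
upregulated
up-regulated
downregulated
down-regulated
overexpressed
overexpression
reduced
diminished
elevated
suppressed
inhibited
deleted
up
down
higher
lower
constant
unchanged
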