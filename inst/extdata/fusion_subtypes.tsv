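gene5	exon5	gene3	exon3	subtype
EWSR1	7	FLI1	6	EWSR1-FLI1 type I
EWSR1	7	FLI1	5	EWSR1-FLI1 type II
EWSR1	7	ERG	6	EWSR1-ERG
EWSR1	7	FEV	2	EWSR1-FEV
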