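domain	category
MNT	TA
HEPN	TA
RelE	TA
Methylase	R-M
REase	R-M
Helicase	R-M
Specificity	R-M
McrC	R-M
Csx1	CRISPR-Cas
Csm6	CRISPR-Cas
Cas2	CRISPR-Cas
AbiV	Abi
AbiEii	Abi
PglX	Pgl
PglZ	Pgl
TerD	TerD
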