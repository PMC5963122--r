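# Example gene list for the keyword "PD" (parkinsonism-associated genes).
# One HGNC symbol per line; '#' starts a comment.
FXN
MFN2
MYOC
NPC1
PSEN1
RET
SPG7
GBA
LRRK2
SNCA
PRKN
PINK1
PARK7
VPS35
DNAJC13
CHCHD2
ATP13A2
UCHL1
GCH1
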