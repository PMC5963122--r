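# Example gene list for the keyword "neuron" (neuronal-function genes).
# One HGNC symbol per line; '#' starts a comment.
FXN
MFN2
MYOC
NPC1
PSEN1
RET
SPG7
SCN3A
SCN1A
SCN2A
GRIN2A
GRIN2B
SYN1
MAPT
BDNF
KCNQ2
CACNA1A
NRXN1
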