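gene	rsid	protein_change	maf_exac	revel	cadd_phred
GBA	rs2230288	E365K	0.0098	0.595	17.33
GBA	rs75548401	T408M	0.0066	0.731	22.2
LRRK2	rs34594498	A419V	0.0005	0.175	24.3
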