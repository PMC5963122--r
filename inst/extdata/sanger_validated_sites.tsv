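location	ad1	ad2	dp	printed_ratio	sanger_result
12:40713899	33	42	75	0.12	present
12:40753203	31	21	52	0.23	NA
12:40758665	86	40	126	0.37	absent
12:40696597	41	13	52	0.54	NA
12:40748293	50	11	58	0.67	NA
12:40653331	76	10	84	0.78	NA
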