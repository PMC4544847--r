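recipient	WK1	MO1	MO2_3
R1	3.4	CNBP	13
R2	3.5	CNBP	CNBP
R3	43.1	47.9	-4.7
R5	52.9	41.1	19.5
R6	43.1	21.1	12.3
R7	1.5	18.2	24.9
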