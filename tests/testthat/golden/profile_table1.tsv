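mie	PAH-B|female|1	PAH-B|female|10	PAH-B|female|100	PAH-B|male|1	PAH-B|male|10	PAH-B|male|100	PFAS-A|female|1	PFAS-A|female|10	PFAS-A|female|100	PFAS-A|male|1	PFAS-A|male|10	PFAS-A|male|100
TF01	0	5	5	0	3	5	0	2	5	0	3	5
TF02	0	0	0	0	0	0	0	0	0	0	0	1
TF03	0	0	1	2	1	1	1	0	1	0	0	0
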