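mie	chemical	class	sex	dose_mg_per_kg	n_up	n_down	n_total	frac_up	frac_down	undefined
TF01	PAH-B	PAH	female	1	0	0	0	NA	NA	TRUE
TF02	PAH-B	PAH	female	1	0	0	0	NA	NA	TRUE
TF03	PAH-B	PAH	female	1	0	0	0	NA	NA	TRUE
TF01	PAH-B	PAH	female	10	5	0	5	1	0	FALSE
TF02	PAH-B	PAH	female	10	0	0	0	NA	NA	TRUE
TF03	PAH-B	PAH	female	10	0	0	0	NA	NA	TRUE
TF01	PAH-B	PAH	female	100	5	0	5	1	0	FALSE
TF02	PAH-B	PAH	female	100	0	0	0	NA	NA	TRUE
TF03	PAH-B	PAH	female	100	0	1	1	0	1	FALSE
TF01	PAH-B	PAH	male	1	0	0	0	NA	NA	TRUE
TF02	PAH-B	PAH	male	1	0	0	0	NA	NA	TRUE
TF03	PAH-B	PAH	male	1	1	1	2	0.5	0.5	FALSE
TF01	PAH-B	PAH	male	10	3	0	3	1	0	FALSE
TF02	PAH-B	PAH	male	10	0	0	0	NA	NA	TRUE
TF03	PAH-B	PAH	male	10	1	0	1	1	0	FALSE
TF01	PAH-B	PAH	male	100	5	0	5	1	0	FALSE
TF02	PAH-B	PAH	male	100	0	0	0	NA	NA	TRUE
TF03	PAH-B	PAH	male	100	1	0	1	1	0	FALSE
TF01	PFAS-A	PFAS	female	1	0	0	0	NA	NA	TRUE
TF02	PFAS-A	PFAS	female	1	0	0	0	NA	NA	TRUE
TF03	PFAS-A	PFAS	female	1	1	0	1	1	0	FALSE
TF01	PFAS-A	PFAS	female	10	2	0	2	1	0	FALSE
TF02	PFAS-A	PFAS	female	10	0	0	0	NA	NA	TRUE
TF03	PFAS-A	PFAS	female	10	0	0	0	NA	NA	TRUE
TF01	PFAS-A	PFAS	female	100	5	0	5	1	0	FALSE
TF02	PFAS-A	PFAS	female	100	0	0	0	NA	NA	TRUE
TF03	PFAS-A	PFAS	female	100	0	1	1	0	1	FALSE
TF01	PFAS-A	PFAS	male	1	0	0	0	NA	NA	TRUE
TF02	PFAS-A	PFAS	male	1	0	0	0	NA	NA	TRUE
TF03	PFAS-A	PFAS	male	1	0	0	0	NA	NA	TRUE
TF01	PFAS-A	PFAS	male	10	3	0	3	1	0	FALSE
TF02	PFAS-A	PFAS	male	10	0	0	0	NA	NA	TRUE
TF03	PFAS-A	PFAS	male	10	0	0	0	NA	NA	TRUE
TF01	PFAS-A	PFAS	male	100	5	0	5	1	0	FALSE
TF02	PFAS-A	PFAS	male	100	1	0	1	1	0	FALSE
TF03	PFAS-A	PFAS	male	100	0	0	0	NA	NA	TRUE
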