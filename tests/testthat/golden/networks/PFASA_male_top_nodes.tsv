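node	type	log2fc	sign_class	dysreg_class
TF01	MIE	-0.001198	down	none
TF02	MIE	-0.246297	down	none
TF03	MIE	-0.152883	down	none
Gene00001	target	1.418712	up	up
Gene00002	target	1.033446	up	up
Gene00003	target	1.34824	up	up
Gene00004	target	1.448551	up	up
Gene00005	target	1.813984	up	up
Gene00006	target	0.608099	up	up
Gene00007	target	0.077143	up	none
Gene00008	target	0.108463	up	none
Gene00009	target	0.442666	up	none
Gene00010	target	-0.130604	down	none
Gene00011	target	-0.00208	down	none
Gene00012	target	0.285042	up	none
Gene00013	target	0.074876	up	none
Gene00014	target	-0.30063	down	none
Gene00015	target	0.036893	up	none
Gene00016	target	-0.334353	down	none
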