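gene	pattern	trend_PAHB_female	trend_PAHB_male	trend_PFASA_female	trend_PFASA_male
TF01	none	none	none	none	none
TF02	none	none	none	none	none
TF03	none	none	none	none	none
Gene00001	consistent_up	up	up	up	none
Gene00002	consistent_up	up	up	none	none
Gene00003	consistent_up	none	up	up	up
Gene00004	consistent_up	none	up	none	up
Gene00005	consistent_up	up	up	up	up
Gene00006	none	none	none	none	up
Gene00007	none	none	none	none	none
Gene00008	none	none	none	none	none
Gene00009	none	none	none	none	none
Gene00010	none	none	none	none	none
Gene00011	none	none	none	none	none
Gene00012	none	none	none	none	none
Gene00013	none	none	none	none	none
Gene00014	none	none	none	none	none
Gene00015	none	down	none	none	none
Gene00016	none	none	none	none	none
Filler00001	none	none	up	none	none
Filler00002	none	none	none	none	none
Filler00003	none	none	up	none	none
Filler00004	none	none	none	none	none
Filler00005	none	none	none	none	none
Filler00006	none	none	none	none	up
Filler00007	none	none	none	none	none
Filler00008	none	none	none	none	none
Filler00009	none	none	none	none	none
Filler00010	none	none	none	none	none
Filler00011	none	none	none	none	none
Filler00012	none	none	none	none	none
Filler00013	none	none	none	none	none
Filler00014	none	none	none	none	none
Filler00015	none	none	none	none	none
Filler00016	none	none	none	none	none
Filler00017	none	none	none	none	none
Filler00018	none	none	none	none	none
Filler00019	none	none	none	none	none
Filler00020	none	none	none	none	none
Filler00021	none	none	none	none	none
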