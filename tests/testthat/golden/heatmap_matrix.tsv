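gene	PAH-B|female|1	PAH-B|female|10	PAH-B|female|100	PAH-B|male|1	PAH-B|male|10	PAH-B|male|100	PFAS-A|female|1	PFAS-A|female|10	PFAS-A|female|100	PFAS-A|male|1	PFAS-A|male|10	PFAS-A|male|100
Gene00003	-0.146034	0.709849	1.29991	0.020882	0.027757	1.307837	0.489035	1.12135	1.508336	0.514068	0.551199	1.34824
Gene00005	0.311136	0.935926	1.336418	0.564514	1.225805	1.517583	0.201534	1.235014	1.638971	0.375961	1.16068	1.813984
Gene00001	0.27895	0.683396	1.475085	0.531885	0.326898	1.381378	0.502027	0.494009	1.076781	-0.01525	0.662005	1.418712
Gene00002	0.040785	0.747409	1.793517	0.362297	0.918552	1.494541	-0.120054	0.552648	1.320169	-0.213966	0.766903	1.033446
Gene00004	-0.103073	0.808809	1.588624	0.557947	1.191429	1.728033	-0.104767	0.407835	1.318566	0.240232	0.471351	1.448551
Gene00006	-0.308204	-0.167081	-0.276968	-0.380947	-0.329671	-0.348536	0.353137	0.325429	-0.219679	0.211405	0.292237	0.608099
Gene00013	0.117394	0.397068	0.331351	-0.753203	-0.132168	-0.193604	0.147321	0.08733	-0.67609	0.116856	-0.036482	0.074876
Gene00010	0.228753	0.137626	0.023601	0.082506	-0.129929	0.277281	0.78515	0.394526	0.535762	0.326407	0.405884	-0.130604
Gene00016	0.041017	-0.109122	-0.108223	0.920498	0.060768	0.622609	0.291837	0.042513	0.033995	-0.351828	-0.085809	-0.334353
Gene00011	-0.348274	-0.055301	-0.208394	0.26531	0.602272	0.312417	0.035707	-0.436865	-0.150295	-0.066515	0.062963	-0.00208
Gene00015	-0.245946	-0.197809	-0.624562	-0.257819	0.019088	0.187339	-0.260341	-0.005394	-0.010542	0.186479	-0.396985	0.036893
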