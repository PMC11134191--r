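group	site	N	Ar	Ho	He	relatedness	Ne
wild	MEW1	30	1.836	0.241	0.271	0.091	189.3
wild	MEW2	31	1.845	0.241	0.272	0.085	360.1
wild	LIW1	31	1.865	0.246	0.271	0.057	158.9
wild	LIW2	30	1.867	0.248	0.272	0.057	10412.8
wild	DBW1	31	1.870	0.242	0.275	0.058	43677.6
wild	DBW2	32	1.873	0.241	0.277	0.058	19722.8
wild	NCW1	32	1.870	0.240	0.277	0.089	12916.2
wild	NCW2	30	1.842	0.232	0.267	0.131	21493.1
wild	DBX1	32	1.803	0.243	0.263	0.147	15.9
selected	DBX2	31	1.767	0.239	0.257	0.200	52.3
selected	DBX3	31	1.843	0.251	0.276	0.136	42.3
selected	UNC1	20	1.722	0.247	0.245	0.290	2.4
selected	UNC2	22	1.702	0.226	0.238	0.318	24.9
selected	UMFS	30	1.711	0.231	0.239	0.311	37.5
selected	NYH1	30	1.454	0.185	0.171	0.610	64.4
selected	NEH1	32	1.810	0.246	0.267	0.176	127.3
selected	NEH2	32	1.781	0.247	0.260	0.204	57.3
selected	MEH2	32	1.665	0.250	0.234	0.334	12.1
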