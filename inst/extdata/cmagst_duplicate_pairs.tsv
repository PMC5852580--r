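id_a	id_b	Ks	Ka	ratio	dup_type	selection	divergence_mya
CmaGSTU3	CmaGSTU4	0.215	0.127	0.593	segmental	purifying	7.18
CmaGSTU4	CmaGSTU5	0.139	0.056	0.405	segmental	purifying	4.66
CmaGSTU12	CmaGSTU14	0.038	0.017	0.452	tandem	purifying	1.30
CmaGSTU12	CmaGSTU13	0.412	0.142	0.346	segmental	purifying	13.75
CmaGSTU12	CmaGSTU15	0.455	0.137	0.302	segmental	purifying	15.19
CmaGSTU12	CmaGSTU16	0.533	0.229	0.430	segmental	purifying	17.78
CmaGSTU13	CmaGSTU14	0.387	0.142	0.367	segmental	purifying	12.91
CmaGSTU13	CmaGSTU15	0.405	0.172	0.424	tandem	purifying	13.52
CmaGSTU13	CmaGSTU16	0.309	0.242	0.784	tandem	purifying	10.32
CmaGSTU14	CmaGSTU15	0.398	0.151	0.379	segmental	purifying	13.27
CmaGSTU15	CmaGSTU16	0.308	0.226	0.735	tandem	purifying	10.28
CmaGSTZ1	CmaGSTZ2	0.382	0.220	0.575	tandem	purifying	12.76
CmaEF1G1	CmaEF1G2	0.080	0.119	1.483	segmental	positive	2.68
CmaEF1G1	CmaEF1G3	0.536	0.293	0.547	segmental	purifying	17.89
CmaEF1G2	CmaEF1G3	0.566	0.279	0.493	segmental	purifying	18.87
CmaGSTT1	CmaGSTT2	0.201	0.130	0.646	segmental	purifying	6.72
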