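variant_id	risk_allele	pooled_or	ci_low	ci_high	p_display	af_cases	af_controls	af_population
rs181489	T	1.28	1.17	1.40	<0.00001	0.3486	0.2974	0.2531
rs356165	G	1.25	1.15	1.37	<0.00001	0.5117	0.4631	0.4601
rs356186	A	0.77	0.70	0.86	<0.00001	0.1629	0.2008	0.194
rs356219	G	1.30	1.23	1.38	<0.00001	0.4723	0.4038	0.4549
rs356220	T	1.23	1.14	1.33	<0.00001	0.4865	0.4363	0.4543
rs356221	A	1.15	0.94	1.40	0.16	0.6257	0.5963	0.5591
rs894278	G	1.13	0.87	1.46	0.37	0.3926	0.3626	0.1479
rs2301134	A	1.00	0.74	1.34	0.97	0.2559	0.2454	0.4248
rs2301135	G	1.24	0.87	1.76	0.23	0.3559	0.3581	0.4179
rs2583988	T	1.21	1.08	1.35	0.001	0.2981	0.2648	0.1982
rs2619363	T	1.13	1.02	1.24	0.01	0.3051	0.2802	0.1887
rs2619364	G	1.24	1.11	1.40	0.0003	0.302	0.2587	0.1891
rs2736990	G	1.22	1.13	1.31	<0.00001	0.6092	0.5602	0.554
rs2737029	G	1.38	1.20	1.59	<0.00001	0.5205	0.4478	0.4505
rs7684318	C	1.53	1.22	1.91	0.0003	0.5913	0.5229	0.1912
rs11931074	T	1.36	1.29	1.44	<0.00001	0.2825	0.2501	0.2344
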