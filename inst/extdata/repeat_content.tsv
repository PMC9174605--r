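species	all_kb	all_pct	tandem_kb	tandem_pct	te_kb	te_pct	dispersed_kb	dispersed_pct	n_all	n_small	n_medium	n_large
Platycladus orientalis	608	23.18	123	4.70	157	6.00	541	20.60	7,634	6,332	1,269	33
Cupressus sempervirens	649	23.66	68	2.48	62	2.26	594	21.65	21,162	20,061	1,101	0
Hesperocyparis glabra	500	25.42	76	3.85	134	6.80	437	22.24	28,579	26,598	1,823	158
Taxus cuspidata	96	20.45	33	6.99	12	2.49	72	15.30	1,157	908	247	2
Podocarpus macrophyllus	202	9.99	19	0.94	32	1.58	167	8.26	1,927	1,520	397	10
Araucaria heterophylla	230	16.62	45	3.24	42	3.04	178	12.84	2,546	1,817	723	6
Gnetum gnemon	203	31.75	29	4.60	22	3.49	171	26.75	22,333	19,944	2,355	34
Welwitschia mirabilis	86	8.83	24	2.49	10	1.06	61	6.22	822	781	41	0
Picea abies	1,320	26.95	101	2.07	463	9.46	1,082	22.09	14,718	11,856	2,825	37
Picea glauca	1,670	27.86	126	2.10	440	7.33	1,411	23.54	19,734	15,853	3,795	86
Pinus lambertiana	1,079	26.82	80	1.99	213	5.29	950	23.63	134,961	126,792	8,157	12
Pinus taeda	281	23.58	60	5.04	94	7.93	242	20.30	51,637	41,842	9,787	8
Larix sibirica	3,899	33.44	132	1.13	1,052	9.02	3,293	28.23	150,913	100,388	50,404	121
Abies sibirica	568	38.24	24	1.60	286	19.26	469	31.54	2,712	1,299	1,195	218
Ginkgo biloba	49	14.13	4	1.04	11	3.21	38	10.92	2,712	2,685	24	3
Ceratozamia hildae	106	25.84	9	2.24	56	13.56	89	21.72	3,054	2,404	643	7
Zamia integrifolia	168	35.76	9	1.95	73	15.57	150	31.92	3,390	2,478	831	81
Cycas taitungensis	122	29.30	22	5.40	10	2.52	111	26.75	42,039	31,747	10,285	7
Amborella trichopoda	1,068	27.62	71	1.83	241	6.24	907	23.47	142,369	113,064	29,249	56
Liriodendron tulipifera	116	20.94	2	0.36	39	7.02	83	15.02	669	564	99	6
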