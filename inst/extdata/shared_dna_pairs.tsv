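species1	species2	t_mya	kb_1to2	kb_2to1	kb_mean	pct_1	pct_2	pct_mean
Platycladus orientalis	Cupressus sempervirens	87	1,573	1,599	1,586	60.0	58.3	59.2
Platycladus orientalis	Podocarpus macrophyllus	226	78	99	88	3.0	4.9	4.0
Cupressus sempervirens	Hesperocyparis glabra	31	1,311	1,344	1,328	47.8	68.4	58.1
Podocarpus macrophyllus	Araucaria heterophylla	126	156	157	156	7.7	11.4	9.6
Gnetum gnemon	Welwitschia mirabilis	112	54	53	54	8.5	5.4	7.0
Platycladus orientalis	Welwitschia mirabilis	252	31	46	38	1.2	4.7	3.0
Picea abies	Welwitschia mirabilis	265	39	54	46	0.8	5.6	3.2
Picea abies	Picea glauca	25	3,808	3,658	3,733	77.7	61.0	69.4
Pinus lambertiana	Pinus taeda	72	677	855	766	16.9	71.8	44.4
Abies sibirica	Pinus taeda	154	176	167	172	11.9	14.1	13.0
Ginkgo biloba	Welwitschia mirabilis	287	37	36	36	10.7	3.7	7.2
Ginkgo biloba	Cycas taitungensis	305	233	226	230	67.5	54.7	61.1
Ceratozamia hildae	Zamia integrifolia	41	344	319	332	83.7	68.2	76.0
Cycas taitungensis	Ceratozamia hildae	194	247	278	262	59.7	67.7	63.7
Cycas taitungensis	Zamia integrifolia	194	244	265	254	58.8	56.6	57.7
Cycas taitungensis	Welwitschia mirabilis	305	36	36	36	8.9	3.8	6.4
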