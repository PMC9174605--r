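lineage	species	genome_size_kb	n_scaffolds	gc_pct	accession
Cupressophytes	Platycladus orientalis	2,624	2	50.60	OL703044-45
Cupressophytes	Cupressus sempervirens	2,743	238	50.64	MN965161-90
Cupressophytes	Hesperocyparis glabra	1,967	129	50.02	MN965210-41
Cupressophytes	Taxus cuspidata	469	1	50.39	MN593023
Cupressophytes	Podocarpus macrophyllus	2,021	85	47.44	MN965338-58
Cupressophytes	Araucaria heterophylla	1,384	52	46.80	MN965108-21
Gnetophytes	Gnetum gnemon	640	44	47.88	MN965191-209
Gnetophytes	Welwitschia mirabilis	979	1	53.02	NC_029130
Pinaceae	Picea abies	4,899	4	44.67	MN642623-626
Pinaceae	Picea glauca	5,995	36	44.67	LKAM00000000
Pinaceae	Pinus lambertiana	4,021	262	44.91	NA
Pinaceae	Pinus taeda	1,191	1	46.67	NC_039746
Pinaceae	Larix sibirica	11,663	9	41.90	MT797187-95
Pinaceae	Abies sibirica	1,485	237	45.73	MN965088-107
Ginkgo	Ginkgo biloba	347	1	50.36	NC_027976
Cycads	Ceratozamia hildae	412	85	47.54	MN965122-60
Cycads	Zamia integrifolia	469	96	47.59	MN965050-87
Cycads	Cycas taitungensis	415	1	46.92	NC_010303
Angiosperm	Amborella trichopoda	3,866	5	45.92	KF754799-803
Angiosperm	Liriodendron tulipifera	554	1	47.70	KC821969
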