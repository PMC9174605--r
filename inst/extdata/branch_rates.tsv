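taxon	clade	is_terminal	is_clade_summary	t_mya	ds	rs_given	dn	rn_given
Platycladus orientalis	Cupressophytes	TRUE	FALSE	87	0.002997	3.44483E-11	0.001498	1.72184E-11
Cupressus sempervirens	Cupressophytes	TRUE	FALSE	31	0.004554	1.46903E-10	0.003375	1.08871E-10
Hesperocyparis glabra	Cupressophytes	TRUE	FALSE	31	0.042915	1.38435E-09	0.037602	1.21297E-09
Cupressaceae	Cupressophytes	FALSE	FALSE	145	0.050927	3.51221E-10	0.016829	1.16062E-10
Taxus cuspidata	Cupressophytes	TRUE	FALSE	145	0.037293	2.57193E-10	0.014685	1.01276E-10
Podocarpus macrophyllus	Cupressophytes	TRUE	FALSE	127	0.137564	1.08318E-09	0.017518	1.37937E-10
Araucaria heterophylla	Cupressophytes	TRUE	FALSE	127	0.077235	6.08150E-10	0.019114	1.50504E-10
Cupressophytes	Cupressophytes	FALSE	TRUE	252	0.064140	2.54524E-10	0.018398	7.30079E-11
Gnetum gnemon	Gnetophytes	TRUE	FALSE	112	0.057119	5.09991E-10	0.027154	2.42446E-10
Welwitschia mirabilis	Gnetophytes	TRUE	FALSE	112	0.126746	1.13166E-09	0.073152	6.53143E-10
Gnetophytes	Gnetophytes	FALSE	TRUE	252	0.053585	2.12639E-10	0.019649	7.79722E-11
Picea abies	Pinaceae	TRUE	FALSE	25	0.005778	2.31120E-10	0.005871	2.34840E-10
Picea glauca	Pinaceae	TRUE	FALSE	25	0.046808	1.87232E-09	0.032513	1.30052E-09
Pinus lambertiana	Pinaceae	TRUE	FALSE	72	0.005949	8.26250E-11	0.005264	7.31111E-11
Pinus taeda	Pinaceae	TRUE	FALSE	72	0.007723	1.07264E-10	0.004264	5.92222E-11
Abies sibirica	Pinaceae	TRUE	FALSE	154	0.069804	4.53273E-10	0.054221	3.52084E-10
Larix sibirica	Pinaceae	TRUE	FALSE	133	0.031210	2.34662E-10	0.007401	5.56466E-11
Pinaceae	Pinaceae	FALSE	TRUE	265	0.009825	3.70755E-11	0.004160	1.56981E-11
Ginkgo biloba	Ginkgo	TRUE	TRUE	287	0.035716	1.24446E-10	0.007753	2.70139E-11
Ceratozamia hildae	Cycads	TRUE	FALSE	41	0.003389	8.26585E-11	0.000312	7.60976E-12
Zamia integrifolia	Cycads	TRUE	FALSE	41	0.011686	2.85024E-10	0.009431	2.30024E-10
Cycas taitungensis	Cycads	TRUE	FALSE	194	0.003073	1.58402E-11	0.001835	9.45876E-12
Cycads	Cycads	FALSE	TRUE	305	0.026821	8.79377E-11	0.005682	1.86295E-11
Amborella trichopoda	Angiosperm	TRUE	FALSE	117	0.025430	2.17350E-10	0.010369	8.86239E-11
Liriodendron tulipifera	Angiosperm	TRUE	FALSE	117	0.026193	2.23872E-10	0.009041	7.72735E-11
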