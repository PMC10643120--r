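protein	accession	times_detected	log2_fold_change	norm_peak_area	annotation	found_in_other_bait
gp175	YP_009217254.1	3	6.99	1.09e-2	UvsX protein (RecA)	no
gp210	YP_009217289.1	3	8.38	2.96e-3	Putative endonuclease	no
gp253	YP_009217332.1	1	7.47	1.59e-3	Hypothetical protein	no
gp222	YP_009217301.1	1	inf	1.46e-3	Hypothetical protein	yes
gp313	YP_009217392.1	2	3.31	7.11e-4	Hypothetical protein	no
gp49	YP_009217132.1	1	3.73	6.16e-4	Hypothetical protein	no
gp358	YP_009217437.1	1	8.02	4.91e-4	Hypothetical protein	yes
gp166	YP_009217245.1	2	inf	2.12e-4	Tail protein	yes
gp78	YP_009217158.1	2	inf	1.71e-4	Endonuclease	yes
gp271	YP_009217350.1	1	5.18	1.41e-4	Hypothetical protein	yes
gp12	YP_009217094.1	1	inf	1.27e-4	Tail protein	yes
gp200	YP_009217279.1	1	inf	1.19e-4	Hypothetical protein	yes
gp233	YP_009217312.1	1	6.33	9.00e-5	SNF2 domain helicase	yes
gp131	YP_009217211.1	1	inf	7.80e-5	Putative helicase	yes
gp308	YP_009217387.1	1	inf	7.22e-5	Hypothetical protein	yes
gp64	YP_009217147.1	1	inf	7.05e-5	Hypothetical protein	yes
gp257	YP_009217336.1	1	4.06	7.04e-5	DNA ligase	yes
gp144	YP_009217223.1	1	inf	6.75e-5	Hypothetical protein	no
gp350	YP_009217429.1	1	inf	5.58e-5	Hypothetical protein	no
gp239	YP_009217318.1	1	inf	4.77e-5	Hypothetical protein	yes
gp108	YP_009217188.1	1	inf	4.48e-5	Hypothetical protein	no
gp217	YP_009217296.1	1	inf	3.10e-5	Hypothetical protein	yes
gp61	YP_009217144.1	1	inf	2.42e-5	Hypothetical protein	yes
gp247	YP_009217326.1	1	inf	1.76e-5	Hypothetical protein	yes
gp375	YP_009217454.1	1	inf	1.70e-5	Hypothetical protein	no
gp62	YP_009217145.1	1	inf	1.69e-5	nvRNAP subunit	yes
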