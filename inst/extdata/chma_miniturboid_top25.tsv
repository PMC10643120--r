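protein	accession	times_detected	log2_fold_change	norm_peak_area	annotation	found_in_other_bait
gp53	YP_009217136.1	3	4.00	3.25e-2	Major nuclear shell protein	no
gp52	YP_009217135.1	3	3.27	2.09e-2	Hypothetical protein	no
gp355	YP_009217434.1	3	3.79	6.49e-3	Hypothetical protein	no
gp164	YP_009217199.1	3	3.93	1.04e-3	Tail protein	no
gp119	YP_009217199.1	3	inf	8.81e-4	Hypothetical protein	yes
gp166	YP_009217245.1	2	inf	8.75e-4	Tail protein	yes
gp358	YP_009217437.1	3	8.51	6.90e-4	Hypothetical protein	yes
gp2	YP_009217084.1	2	inf	5.87e-4	Hypothetical protein	no
gp134	YP_009217213.1	3	inf	5.00e-4	Putative helicase	yes
gp131	YP_009217211.1	2	inf	3.45e-4	Putative helicase	yes
gp63	YP_009217146.1	2	inf	2.85e-4	Hypothetical protein	yes
gp62	YP_009217145.1	2	inf	2.51e-4	nvRNAP subunit	yes
gp222	YP_009217301.1	2	inf	2.13e-4	Hypothetical protein	yes
gp106	YP_009217186.1	2	6.10	1.57e-4	Virion structural protein	no
gp18	YP_009217100.1	1	inf	1.57e-4	Hypothetical protein	yes
gp202	YP_009217281.1	1	inf	1.55e-4	Hypothetical protein	no
gp148	YP_009217227.1	1	inf	1.20e-4	Portal protein	no
gp14	YP_009217096.1	1	4.95	1.08e-4	Hypothetical protein	no
gp12	YP_009217094.1	1	inf	9.40e-5	Tail protein	yes
gp378	YP_009217457.1	2	inf	8.48e-5	NrdA	no
gp247	YP_009217326.1	1	inf	4.45e-5	Hypothetical protein	yes
gp257	YP_009217336.1	2	3.21	3.90e-5	DNA ligase	yes
gp219	YP_009217298.1	1	inf	3.87e-5	Hypothetical protein	no
gp335	YP_009217414.1	1	inf	3.83e-5	Hypothetical protein	yes
gp85	YP_009217165.1	1	inf	3.67e-5	Hypothetical protein	no
gp370	YP_009217449.1	1	inf	2.79e-5	Hypothetical protein	no
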