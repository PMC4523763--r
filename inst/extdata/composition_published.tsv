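label	group	locus	gc_skew	gc_content
Valdieri	ingroup	COI	-0.189	40.0
Vernante	ingroup	COI	-0.183	39.7
Barbarano	ingroup	COI	-0.176	38.2
Volpago	ingroup	COI	-0.246	45.9
Giavera	ingroup	COI	-0.136	38.6
Lovran	ingroup	COI	-0.201	41.4
Isola Fossara	ingroup	COI	-0.237	43.0
Frasassi	ingroup	COI	-0.244	42.5
Frosinone	ingroup	COI	-0.244	41.4
Randazzo	ingroup	COI	-0.206	40.6
Cyprus	ingroup	COI	-0.188	46.8
Iran	ingroup	COI	-0.218	43.9
Arctogeophilus glacialis	outgroup	COI	-0.254	46.9
Clinopodes carinthiacus	outgroup	COI	-0.156	41.1
Geophilus alpinus	outgroup	COI	-0.235	47.3
Geophilus electricus	outgroup	COI	-0.217	43.4
Geophilus flavus	outgroup	COI	-0.232	42.4
Tuoba sydneyensis	outgroup	COI	-0.205	39.3
Valdieri	ingroup	28S	0.051	61.0
Vernante	ingroup	28S	0.053	60.9
Barbarano	ingroup	28S	0.054	59.3
Giavera	ingroup	28S	0.044	61.5
Lovran	ingroup	28S	0.051	57.5
Isola Fossara	ingroup	28S	0.047	59.3
Frasassi	ingroup	28S	0.054	59.8
Frosinone	ingroup	28S	0.058	61.1
Randazzo	ingroup	28S	0.056	61.5
Cyprus	ingroup	28S	0.069	61.8
Iran	ingroup	28S	0.040	62.1
Arctogeophilus glacialis	outgroup	28S	0.049	55.7
Clinopodes carinthiacus	outgroup	28S	0.068	61.0
Geophilus alpinus	outgroup	28S	0.080	57.5
Geophilus electricus	outgroup	28S	0.072	58.1
Geophilus flavus	outgroup	28S	0.063	61.5
Tuoba sydneyensis	outgroup	28S	0.055	59.7
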