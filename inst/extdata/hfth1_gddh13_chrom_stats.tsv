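genome	chrom	length	n_gaps	telomere
HFTH1	Chr01	32944118	12	Single
HFTH1	Chr02	38449405	8	Both
HFTH1	Chr03	37138690	4	Single
HFTH1	Chr04	31012745	7	Both
HFTH1	Chr05	47891858	13	Single
HFTH1	Chr06	35567198	5	Both
HFTH1	Chr07	35934761	5	Both
HFTH1	Chr08	31511015	7	Single
HFTH1	Chr09	34800404	9	Single
HFTH1	Chr10	43815736	13	Both
HFTH1	Chr11	42456296	14	Single
HFTH1	Chr12	32285079	8	Single
HFTH1	Chr13	44866511	12	Single
HFTH1	Chr14	31515206	5	Both
HFTH1	Chr15	56644392	15	-
HFTH1	Chr16	41670059	14	-
HFTH1	Chr17	33998825	7	Both
HFTH1	mtDNA	396939	0	NA
HFTH1	cpDNA	160068	0	NA
HFTH1	Unanchored	7992922	326	-
GDDH13	Chr01	32625452	85	Single
GDDH13	Chr02	37577729	87	-
GDDH13	Chr03	37524076	80	-
GDDH13	Chr04	32301874	64	Single
GDDH13	Chr05	47952461	107	-
GDDH13	Chr06	37137259	88	Single
GDDH13	Chr07	36691129	75	-
GDDH13	Chr08	31609270	66	Single
GDDH13	Chr09	37604908	79	Single
GDDH13	Chr10	41762413	82	Single
GDDH13	Chr11	43059885	90	-
GDDH13	Chr12	33050054	74	-
GDDH13	Chr13	44339518	118	Single
GDDH13	Chr14	32513452	61	Single
GDDH13	Chr15	54945402	128	Single
GDDH13	Chr16	41389449	92	-
GDDH13	Chr17	34748701	75	-
GDDH13	mtDNA	396947	0	NA
GDDH13	cpDNA	160068	0	NA
GDDH13	Unanchored	52728359	839	-
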