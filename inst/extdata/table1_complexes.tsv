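pdb_id	protein	resolution	n_p	n_l	n_tors
2Z8D	GNB/LNB-binding protein	1.9	5897	51	6
2Z8E	GNB/LNB-binding protein	2.0	5897	51	6
2XII	alpha-fucosidase	1.8	7042	51	4
3KIV	KIV-10 module of Apo (a)	1.8	1206	20	5
4MR5	BET protein	1.6	1860	42	3
4MR6	BET protein	1.7	1860	49	6
1HW5	CRP	1.8	3284	33	1
1C5P	Trypsin	1.4	3220	18	1
1K1J	Trypsin	2.2	3220	68	10
2ZDM	Trypsin	1.9	3220	59	9
2ZDN	Trypsin	2.0	3220	58	9
2ZFS	Trypsin	1.5	3220	64	9
4P8V	YKL-39	1.6	5741	57	8
4CRC	Factor XIa	1.6	3711	60	11
4CRD	Factor XIa	2.1	3692	57	11
1J84	EngF	2.0	2642	87	10
5CSD	Mp1p-LBD2	1.5	2407	53	14
1MRX	HIV-1 protease	2.0	3140	74	11
1MSM	HIV-1 protease	2.0	3138	78	12
2PYM	HIV-1 protease	1.9	3100	86	12
2PYN	HIV-1 protease	1.9	3116	86	12
3KDB	HIV-1 protease	1.7	3138	86	13
3NU3	HIV-1 protease	1.0	3134	70	13
4LL3	HIV-1 protease	2.0	3134	75	13
2IKO	Renin	1.9	5144	46	5
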