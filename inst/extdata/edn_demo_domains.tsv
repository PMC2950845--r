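protein_id	domain_accession	start	end	evalue
p01	IPR001638	10	240	1.2e-45
p02	IPR001638	5	230	3.0e-40
p03	IPR015683	1	310	8.0e-52
p04	IPR001638	12	245	2.1e-44
p04	IPR001638	15	240	6.3e-12
p04	IPR015683	1	330	1.0e-50
p05	IPR001638	11	242	4.4e-43
p05	IPR015683	2	325	2.2e-49
p06	IPR001638	14	250	7.7e-41
p06	IPR015683	1	340	1.5e-48
p06	IPR013099	255	300	3.8e-09
p07	IPR001638	13	246	9.9e-42
p07	IPR015683	3	338	5.5e-47
p07	IPR013099	252	298	6.1e-10
p08	IPR001638	16	244	8.8e-40
p08	IPR015683	2	335	4.0e-46
p08	IPR001320	30	210	2.5e-20
p09	IPR001638	18	247	5.6e-39
p09	IPR015683	4	342	3.3e-45
p09	IPR001320	28	208	1.9e-21
p09	IPR001508	400	700	7.2e-30
p94	IPR000515	60	240	4.7e-25
p94	IPR013099	250	297	9.4e-08
p94	IPR015590	310	400	5.0e-01
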