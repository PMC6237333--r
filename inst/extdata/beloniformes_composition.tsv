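# Published whole-genome base composition and strand skews of 27 Beloniformes
# mitogenomes (plus concatenated-PCG skews), transcribed from the comparative
# summary table. Percentages of the H strand; skews dimensionless.
family	species	accession	size_bp	A_pct	G_pct	T_pct	C_pct	AT_pct	at_skew	gc_skew	pcg_at_skew	pcg_gc_skew
Adrianichthyidae	Oryzias curvinotus	NC_034775.1	16676	27.72	17.40	26.48	28.41	56.13	-0.0124	-0.2069	-0.1015	-0.2350
Adrianichthyidae	Oryzias dancena	GU013789.1	16863	29.00	16.52	23.85	30.63	59.63	-0.0272	-0.1814	-0.1194	-0.1984
Adrianichthyidae	Oryzias javanicus	GU013790.1	16890	26.77	17.78	28.12	27.32	54.10	-0.0102	-0.2253	-0.1127	-0.2512
Adrianichthyidae	Oryzias latipes	NC_004387.1	16714	27.26	17.95	26.52	28.28	55.53	-0.0183	-0.1927	-0.1156	-0.2264
Adrianichthyidae	Oryzias luzonensis	NC_012979.1	16666	26.42	18.62	27.63	27.34	53.76	-0.0171	-0.1948	-0.1154	-0.2155
Adrianichthyidae	Oryzias melastigma	NC_018546.1	16864	28.94	16.53	23.82	30.71	59.65	-0.0297	-0.1806	-0.1210	-0.1954
Adrianichthyidae	Oryzias minutillus	NC_012975.1	16953	29.31	17.31	24.01	29.36	58.67	-0.0009	-0.1621	-0.0986	-0.1756
Adrianichthyidae	Oryzias sarasinorum	AB370891.1	16462	29.18	17.16	24.93	28.73	57.91	0.0339	-0.2740	-0.0900	-0.2031
Adrianichthyidae	Oryzias sinensis	NC_013434.1	16654	29.21	16.37	26.57	27.85	57.05	0.0077	0.1846	0.0900	0.2031
Adrianichthyidae	Xenopoecilus sarasinorum	NC_011172.1	16462	29.18	17.16	24.93	28.73	57.91	0.0077	-0.1846	-0.0900	-0.2031
Belonidae	Strongylura anastomella	NC_026998.1	16654	29.21	16.37	26.57	27.85	57.05	0.0077	0.1846	0.0900	0.2031
Belonidae	Tylosurus acus	KU605633.1	16723	29.03	17.13	26.22	27.62	56.65	0.0249	-0.2097	-0.0456	-0.2220
Belonidae	Ablennes hians	NC_011180.1	16825	30.00	14.65	27.09	28.26	58.26	0.0298	-0.2980	-0.0496	-0.3447
Exocoetidae	Parexocoetus brachypterus	NC_036719.1	16776	29.05	15.90	27.91	27.14	56.19	0.0339	0.2740	-0.0513	-0.3113
Exocoetidae	Prognichthys sealei	NC_036722.1	16527	27.80	17.46	26.17	28.58	56.38	-0.0137	-0.1997	-0.0612	-0.2717
Exocoetidae	Cheilopogon agoo	NC_036720.1	16526	29.47	16.10	26.92	27.51	56.98	0.0345	-0.2514	-0.0493	-0.2885
Exocoetidae	Cheilopogon atrisignis	NC_029730.1	16530	28.77	16.64	27.34	27.24	56.01	0.0273	-0.2433	-0.0553	-0.2770
Exocoetidae	Cheilopogon cyanopterus	NC_036721.1	16529	28.92	16.49	27.35	27.24	56.16	0.0298	-0.2476	-0.0536	-0.2813
Exocoetidae	Cheilopogon doederleinii	NC_033541.1	16525	29.23	16.30	27.16	27.32	56.54	0.0338	-0.2500	-0.0495	-0.2820
Exocoetidae	Cheilopogon unicolor	NC_029728.1	16529	29.06	16.40	27.24	27.31	56.37	0.0310	-0.2485	-0.0511	-0.2813
Exocoetidae	Cypselurus hiraii	NC_007403.1	16528	29.91	15.63	26.83	27.56	57.47	0.0409	-0.2638	-0.0360	-0.3034
Exocoetidae	Exocoetus volitans	NC_003184.1	16527	28.35	17.12	27.19	27.34	55.69	0.0180	-0.2273	-0.0658	-0.2594
Hemiramphidae	Hyporhamphus intermedius	NC_026467.1	16720	26.71	16.59	27.08	29.62	56.33	-0.0517	-0.2401	-0.1519	-0.2652
Hemiramphidae	Hyporhamphus sajori	AB370892.1	16721	26.69	16.61	27.84	28.86	55.55	-0.0391	-0.2527	-0.1396	-0.2802
Hemiramphidae	Hyporhamphus quoyi	MG851912.1	16525	29.28	15.33	27.86	27.53	56.80	0.0307	-0.2899	-0.0598	-0.3195
Scomberesocidae	Cololabis saira	NC_003183.1	16499	30.42	14.76	25.73	29.09	59.51	0.0224	-0.2711	-0.0704	-0.2986
Zenarchopteridae	Dermogenys pusilla	NC_034337.1	16529	30.70	14.60	26.50	28.19	58.89	0.0425	-0.2895	-0.0442	-0.3340
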