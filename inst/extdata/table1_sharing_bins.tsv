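# Per-bin counts of intergeneric-shared Alu insertion polymorphisms among 12 Papio
# individuals (two per species, northern then southern clade). `total` is the number
# of loci whose ingroup carrier count equals `bin`; the individual columns give the
# number of those loci in which that individual is a carrier. Sum of `total` = 12956.
#species	-	anubis	anubis	hamadryas	hamadryas	papio	papio	cynocephalus	cynocephalus	ursinus	ursinus	kindae	kindae
#clade	-	north	north	north	north	north	north	south	south	south	south	south	south
bin	total	LIV5	L142	97124	97074	28547	30388	16066	16098	28697	28755	34449	34474
2	1139	112	122	192	179	136	146	127	140	155	111	486	372
3	989	174	169	210	205	166	184	227	231	249	185	537	430
4	944	296	248	268	261	206	259	282	297	343	247	567	502
5	839	294	290	248	280	241	294	342	375	413	310	574	534
6	938	396	396	360	381	370	396	491	497	531	421	727	662
7	851	495	466	448	456	395	430	497	480	505	428	702	655
8	991	626	638	631	645	546	617	623	663	677	584	849	829
9	1171	899	865	830	851	811	869	824	862	894	759	1040	1035
10	1881	1659	1635	1531	1522	1442	1516	1501	1563	1590	1405	1732	1714
11	3213	2980	2971	2890	2907	2966	3104	2811	2884	3025	2636	3079	3090
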