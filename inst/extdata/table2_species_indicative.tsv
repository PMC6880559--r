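# Species-indicative Alu insertions (present in both sampled individuals of one
# ingroup species, absent from the other ten) and how many of each set are shared
# with the intergeneric individual, with the published percentage, z-score and
# one-tailed normal p-value.
species	clade	n_indicative	n_shared	pct_shared	z	p_one_tailed
anubis	north	4645	34	0.73	-0.6821	0.2476
hamadryas	north	8060	101	1.25	0.1802	0.4285
papio	north	10873	68	0.63	-0.2445	0.4036
cynocephalus	south	2794	26	0.93	-0.7851	0.2162
ursinus	south	9545	57	0.60	-0.3861	0.3498
kindae	south	12891	236	1.83	1.9176	0.0276
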