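label	nacl_mM	k_ass	k_ass_sd	k_diss	k_diss_sd	KD	KD_sd
PBS (no NaCl)	0	43000	2000	1e-04	5e-05	2.3e-09	1.2e-09
PBS + 25 mM NaCl	25	39000	4000	4e-04	2e-04	1.0e-08	5e-09
PBS + 50 mM NaCl	50	40000	2500	7e-04	1e-04	1.8e-08	3e-09
PBS + 140 mM NaCl	140	41000	6000	2.5e-03	6e-04	6.1e-08	1.7e-08
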