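label	k_ass	k_ass_sd	k_diss	k_diss_sd	KD	KD_sd
ATI	41000	6000	2.5e-03	6e-04	6.1e-08	1.7e-08
ATI nonreduced digest	6000	400	2.9e-03	4e-04	4.8e-07	7e-08
ATI reduced digest	3000	350	7.7e-03	1.0e-03	2.6e-06	5e-07
RSGNVGESGLI peptide	3620	280	5.0e-03	1.2e-03	1.4e-06	4e-07
scrambled SGIVLSGGNRE	NA	NA	NA	NA	9.9e-06	NA
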