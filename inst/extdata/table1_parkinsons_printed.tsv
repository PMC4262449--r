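dataset	samples	mean_control	mean_case	wilcoxon_p	perm_p	inversion_pct	inversion_perm_p	include_in_meta
GSE6613_Scherzer_blood	105	-0.115	-0.115	0.85	0.508	4.48	0.974	FALSE
GSE7621_Lesnick	25	-0.166	0.099	4.30e-05	0.101	57.14	0.037	TRUE
GSE8397_Moran	39	-0.231	-0.036	3.32e-04	0.086	32.84	0.046	TRUE
GSE20295_Zhang	29	-0.154	-0.014	0.020	0.219	31.25	0.115	TRUE
GSE20159_Zheng	33	-0.040	0.183	6.06e-04	0.045	34.62	0.014	TRUE
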