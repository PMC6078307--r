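circuit	block_a	variable_a	block_b	variable_b	modality	r	p	p_lt	q	q_lt	df
amygdala_nacc	metabolite	Indole	brain	B_R_NAcc	functional	0.59608	0.001	TRUE	0.001	TRUE	62
amygdala_nacc	metabolite	IAA	brain	S_R_Amg	functional	0.37640	0.003	FALSE	0.011	FALSE	62
amygdala_nacc	metabolite	Indole	brain	S_R_NAcc	functional	0.36637	0.004	FALSE	0.011	FALSE	62
amygdala_nacc	metabolite	IAA	brain	S_R_NAcc	functional	0.33201	0.009	FALSE	0.018	FALSE	62
amygdala_nacc	metabolite	Skatole	brain	S_R_NAcc	functional	0.31022	0.015	FALSE	0.022	FALSE	62
amygdala_nacc	metabolite	Skatole	brain	S_L_NAcc	functional	0.33839	0.008	FALSE	0.046	FALSE	62
amygdala_nacc	clinical	YFAS	brain	S_L_NAcc	functional	0.59632	0.001	TRUE	0.001	TRUE	41
amygdala_nacc	clinical	ANX	brain	S_L_NAcc	functional	0.29999	0.019	FALSE	0.056	FALSE	62
amygdala_nacc	clinical	YFAS	brain	S_R_NAcc	functional	0.36944	0.019	FALSE	0.114	FALSE	62
amygdala_nacc	metabolite	Skatole	brain	S_L_Amg	anatomical	0.55362	0.001	TRUE	0.001	TRUE	61
amygdala_nacc	metabolite	Skatole	clinical	YFAS	NA	0.48043	0.002	FALSE	0.017	FALSE	41
amygdala_nacc	metabolite	Indole	clinical	ANX	NA	-0.28741	0.025	FALSE	0.086	FALSE	62
amygdala_nacc	metabolite	Indole	clinical	BMI	NA	0.28036	0.029	FALSE	0.090	FALSE	62
amygdala_ains	metabolite	IAA	brain	S_R_Amg	functional	0.37639	0.003	FALSE	0.042	FALSE	62
amygdala_ains	metabolite	Skatole	brain	B_L_ALSVerp	functional	0.33542	0.008	FALSE	0.123	FALSE	62
amygdala_ains	metabolite	IAA	brain	S_R_ALSVerp	functional	0.27091	0.035	FALSE	0.206	FALSE	62
amygdala_ains	metabolite	IAA	brain	S_L_ALSHorp	functional	0.26168	0.042	FALSE	0.625	FALSE	62
amygdala_ains	clinical	YFAS	brain	B_L_ALSVerp	functional	0.53843	0.001	TRUE	0.005	FALSE	41
amygdala_ains	clinical	BMI	brain	B_R_ShoInG	functional	0.29197	0.022	FALSE	0.336	FALSE	62
amygdala_ains	metabolite	Skatole	brain	S_L_Amg	anatomical	0.55362	0.001	TRUE	0.001	TRUE	61
amygdala_ains	metabolite	Indole	brain	B_L_ALSHorp	anatomical	0.49712	0.001	TRUE	0.001	TRUE	61
amygdala_ains	metabolite	Skatole	brain	S_R_ALSHorp	anatomical	0.31036	0.016	FALSE	0.237	FALSE	61
amygdala_ains	metabolite	Skatole	brain	S_R_ALSVerp	anatomical	0.26351	0.042	FALSE	0.314	FALSE	61
amygdala_ains	metabolite	Skatole	brain	B_R_ALSHorp	anatomical	0.25465	0.050	TRUE	0.503	FALSE	61
amygdala_ains	clinical	BMI	brain	B_L_ShoInG	anatomical	0.30157	0.019	FALSE	0.288	FALSE	61
amygdala_ains	metabolite	Skatole	clinical	YFAS	NA	0.48043	0.002	FALSE	0.017	FALSE	41
amygdala_ains	metabolite	Indole	clinical	ANX	NA	-0.28741	0.025	FALSE	0.086	FALSE	62
amygdala_ains	metabolite	Indole	clinical	BMI	NA	0.28036	0.029	FALSE	0.090	FALSE	62
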