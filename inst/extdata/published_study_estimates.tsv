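analysis	study	or	ci_low	ci_high	se	published_meta_or	published_i2
la_bmi_interaction_6p24	study1	0.95	0.93	0.98	NA	0.95	0
la_bmi_interaction_6p24	study2	0.95	0.91	1.00	NA	0.95	0
la_bmi_obese_6p24	study1	0.54	0.38	0.77	NA	0.51	0
la_bmi_obese_6p24	study2	0.41	0.21	0.81	NA	0.51	0
la_overall_6p24	study1	0.77	0.60	0.98	NA	0.74	0
la_overall_6p24	study2	0.63	0.39	1.02	NA	0.74	0
snp_bmicat_trend_6p24	study1	1.49	NA	NA	0.11	1.50	0
snp_bmicat_trend_6p24	study2	1.55	NA	NA	0.22	1.50	0
snp_obese_6p24	study1	1.65	NA	NA	0.12	1.66	0
snp_obese_6p24	study2	1.73	NA	NA	0.23	1.66	0
snp_bmicat_trend_2q31	study1	1.40	NA	NA	0.12	1.29	0
snp_bmicat_trend_2q31	study2	1.26	NA	NA	0.23	1.29	0
snp_bmicat_trend_2q31	study3	1.22	NA	NA	0.11	1.29	0
race_normal_weight	study1	0.52	0.43	0.64	NA	0.47	NA
race_normal_weight	study2	0.18	0.10	0.32	NA	0.47	NA
la_overweight_2q31	study1	0.60	0.37	0.97	NA	0.74	74
la_overweight_2q31	study2	1.81	0.68	4.86	NA	0.74	74
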