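clone_id	tp	fp	n_pos	n_neg
Clone_01	12	5	30	30
Clone_02	4	0	30	30
Clone_03	8	3	30	30
Clone_04	7	2	30	30
Clone_05	4	0	30	30
Clone_06	5	1	30	30
Clone_07	9	3	30	30
Clone_08	9	2	30	30
Clone_09	10	3	30	30
Clone_10	5	1	30	30
Clone_11	8	1	30	30
Clone_12	4	0	30	30
Clone_13	5	1	30	30
Clone_14	12	4	30	30
Clone_15	6	1	30	30
Clone_16	11	3	30	30
Clone_17	8	2	30	30
Clone_18	7	2	30	30
Clone_19	9	3	30	30
Clone_20	5	1	30	30
Clone_21	4	0	30	30
Clone_22	5	0	30	30
Clone_23	13	5	30	30
Clone_24	8	3	30	30
Clone_25	4	0	30	30
Clone_26	5	1	30	30
Clone_27	11	3	30	30
Clone_28	9	3	30	30
Clone_29	10	4	30	30
Clone_30	6	1	30	30
Clone_31	4	0	30	30
Clone_32	9	3	30	30
Clone_33	6	1	30	30
Clone_34	12	5	30	30
Clone_35	5	1	30	30
Clone_36	8	3	30	30
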