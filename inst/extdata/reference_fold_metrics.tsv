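experiment	loss	fold	precision	sensitivity	f1
baseline	dice	1	49.21	79.19	60.7
baseline	dice	2	58.74	64.98	61.7
baseline	dice	3	70.56	60.01	64.86
baseline	dice	4	81.69	52.2	63.7
baseline	dice	5	60.57	54.06	57.13
baseline	dice	6	72.55	45.92	56.24
baseline	dice	7	43.63	83.32	57.27
baseline	dice	8	49.03	68.21	57.05
baseline	dice	9	61.73	60.84	61.28
baseline	dice	10	67.89	61.13	64.34
baseline	dice	mean	61.56	62.99	62.27
otsu	dice	1	68.74	67.72	68.23
otsu	dice	2	71.29	56.75	63.2
otsu	dice	3	70.11	64.57	67.23
otsu	dice	4	83.92	58.39	68.86
otsu	dice	5	64.06	58.32	61.06
otsu	dice	6	77.01	53.1	62.86
otsu	dice	7	60.52	73.99	66.58
otsu	dice	8	51.3	65.19	57.41
otsu	dice	9	63.24	64.24	63.73
otsu	dice	10	66.14	70.58	68.29
otsu	dice	mean	67.63	63.29	65.39
otsu	focal_tversky	1	66.95	68.81	67.86
otsu	focal_tversky	2	69.91	60.7	64.98
otsu	focal_tversky	3	69.69	68.49	69.09
otsu	focal_tversky	4	85.19	56.34	67.82
otsu	focal_tversky	5	65.52	60.17	62.73
otsu	focal_tversky	6	79.24	51.88	62.7
otsu	focal_tversky	7	60.64	76.05	67.47
otsu	focal_tversky	8	52.36	68.9	59.5
otsu	focal_tversky	9	62.55	66.4	64.42
otsu	focal_tversky	10	66.66	72.67	69.54
otsu	focal_tversky	mean	67.87	65.04	66.43
otsu_neg	dice	1	70.41	65.42	67.82
otsu_neg	dice	2	70.85	60.72	65.39
otsu_neg	dice	3	73.88	64.55	68.9
otsu_neg	dice	4	85.21	54.91	66.78
otsu_neg	dice	5	71.95	55.89	62.91
otsu_neg	dice	6	82.09	49.93	62.1
otsu_neg	dice	7	62.14	67.76	64.83
otsu_neg	dice	8	54.31	65.79	59.5
otsu_neg	dice	9	65.37	63.09	64.21
otsu_neg	dice	10	66.14	69.9	67.97
otsu_neg	dice	mean	70.24	61.8	65.75
otsu_neg	focal_tversky	1	69.66	67.94	68.79
otsu_neg	focal_tversky	2	70.09	63.16	66.44
otsu_neg	focal_tversky	3	72.29	67.43	69.78
otsu_neg	focal_tversky	4	85.29	56.55	68.01
otsu_neg	focal_tversky	5	72.86	53.82	61.91
otsu_neg	focal_tversky	6	82.54	51.38	63.34
otsu_neg	focal_tversky	7	62.22	72.58	67
otsu_neg	focal_tversky	8	54.42	64.25	58.93
otsu_neg	focal_tversky	9	63.23	64.94	64.07
otsu_neg	focal_tversky	10	66.98	73.49	70.08
otsu_neg	focal_tversky	mean	69.96	63.55	66.6
mining	dice	1	65.94	72.63	69.13
mining	dice	2	71.47	59.26	64.8
mining	dice	3	70.63	61.13	65.54
mining	dice	4	82.85	48.77	61.4
mining	dice	5	57.72	57.81	57.76
mining	dice	6	78.32	45.99	57.95
mining	dice	7	49.5	82.3	61.82
mining	dice	8	50.25	73.06	59.55
mining	dice	9	59.42	68.06	63.45
mining	dice	10	70	63.57	66.63
mining	dice	mean	65.61	63.26	64.41
mining	focal_tversky	1	65.01	70.95	67.85
mining	focal_tversky	2	65.7	62.18	63.89
mining	focal_tversky	3	67.49	68.33	67.91
mining	focal_tversky	4	80.04	60.92	69.19
mining	focal_tversky	5	40.43	78.88	53.46
mining	focal_tversky	6	64.76	60.65	62.64
mining	focal_tversky	7	51.5	80.99	62.97
mining	focal_tversky	8	48.97	70.11	57.66
mining	focal_tversky	9	52.04	74	61.11
mining	focal_tversky	10	57.81	79.95	67.1
mining	focal_tversky	mean	59.38	70.7	64.54
mining_neg	dice	1	64.79	69.79	67.19
mining_neg	dice	2	70.67	59.4	64.55
mining_neg	dice	3	77.27	48.05	59.26
mining_neg	dice	4	85.56	53.52	65.85
mining_neg	dice	5	57.46	63.47	60.32
mining_neg	dice	6	80.69	46.1	58.68
mining_neg	dice	7	57.06	73.52	64.25
mining_neg	dice	8	54.72	62.98	58.56
mining_neg	dice	9	65.6	62.07	63.79
mining_neg	dice	10	60.75	74.89	67.08
mining_neg	dice	mean	67.46	61.38	64.28
mining_neg	focal_tversky	1	59.59	76.92	67.16
mining_neg	focal_tversky	2	59.27	71.75	64.92
mining_neg	focal_tversky	3	67.96	62.61	65.18
mining_neg	focal_tversky	4	83.36	54.1	65.62
mining_neg	focal_tversky	5	46.52	69.61	55.77
mining_neg	focal_tversky	6	74.92	59.45	66.29
mining_neg	focal_tversky	7	48.79	81.93	61.16
mining_neg	focal_tversky	8	50.79	71	59.22
mining_neg	focal_tversky	9	60.26	65.43	62.74
mining_neg	focal_tversky	10	58.71	73.35	65.22
mining_neg	focal_tversky	mean	61.02	68.62	64.59
transfer	dice	1	67.81	70.28	69.02
transfer	dice	2	71.44	63.75	67.38
transfer	dice	3	76.75	60.73	67.8
transfer	dice	4	86.56	51.54	64.61
transfer	dice	5	68.88	62.84	65.72
transfer	dice	6	84.14	43.46	57.31
transfer	dice	7	62.07	66.34	64.14
transfer	dice	8	51.9	72.17	60.38
transfer	dice	9	62.3	64.44	63.35
transfer	dice	10	64.98	74.47	69.4
transfer	dice	mean	69.68	63	66.17
transfer	focal_tversky	1	66.51	72.04	69.17
transfer	focal_tversky	2	70.8	60.64	65.33
transfer	focal_tversky	3	69.87	69.25	69.56
transfer	focal_tversky	4	81.8	60.28	69.41
transfer	focal_tversky	5	51.28	66.78	58.01
transfer	focal_tversky	6	80	52.2	63.18
transfer	focal_tversky	7	50.69	86.04	63.8
transfer	focal_tversky	8	43.82	85.62	57.97
transfer	focal_tversky	9	52.07	77.78	62.38
transfer	focal_tversky	10	63.92	77.56	70.09
transfer	focal_tversky	mean	63.08	70.82	66.72
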