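# Ear traits of the check hybrid CK (Zheng58 x lx9801) and the test hybrid
# HY (Zheng58 x lx9801-hlEW2b) in six environments (E1-E6), mean +/- SD.
# "Average" rows carry the published per-trait averages across environments.
trait	environment	genotype	mean	sd
ear_width_mm	E1	CK	50.71	1.00
ear_width_mm	E1	HY	52.70	1.30
ear_width_mm	E2	CK	46.16	0.96
ear_width_mm	E2	HY	47.64	1.32
ear_width_mm	E3	CK	51.24	0.65
ear_width_mm	E3	HY	53.08	1.11
ear_width_mm	E4	CK	50.09	1.43
ear_width_mm	E4	HY	53.12	1.26
ear_width_mm	E5	CK	51.18	1.50
ear_width_mm	E5	HY	55.49	1.23
ear_width_mm	E6	CK	52.22	1.61
ear_width_mm	E6	HY	56.47	1.45
ear_width_mm	Average	CK	50.27	1.19
ear_width_mm	Average	HY	53.08	1.28
axile_width_mm	E1	CK	29.07	0.37
axile_width_mm	E1	HY	31.67	0.24
axile_width_mm	E2	CK	33.80	1.23
axile_width_mm	E2	HY	34.33	0.97
axile_width_mm	E3	CK	33.49	1.41
axile_width_mm	E3	HY	35.36	2.09
axile_width_mm	E4	CK	33.46	1.58
axile_width_mm	E4	HY	34.52	1.08
axile_width_mm	E5	CK	31.56	1.03
axile_width_mm	E5	HY	32.33	0.94
axile_width_mm	E6	CK	32.93	1.16
axile_width_mm	E6	HY	35.44	1.25
axile_width_mm	Average	CK	32.39	1.13
axile_width_mm	Average	HY	33.94	1.10
ear_length_cm	E1	CK	19.18	0.77
ear_length_cm	E1	HY	19.25	0.78
ear_length_cm	E2	CK	18.56	1.14
ear_length_cm	E2	HY	19.10	0.75
ear_length_cm	E3	CK	19.44	0.85
ear_length_cm	E3	HY	18.86	1.30
ear_length_cm	E4	CK	18.35	1.49
ear_length_cm	E4	HY	17.58	0.93
ear_length_cm	E5	CK	17.24	1.20
ear_length_cm	E5	HY	17.90	0.96
ear_length_cm	E6	CK	16.99	1.24
ear_length_cm	E6	HY	17.27	0.73
ear_length_cm	Average	CK	18.29	1.12
ear_length_cm	Average	HY	18.33	0.91
kernel_row_number	E1	CK	13.80	1.48
kernel_row_number	E1	HY	14.40	0.84
kernel_row_number	E2	CK	13.60	1.26
kernel_row_number	E2	HY	13.40	1.65
kernel_row_number	E3	CK	13.40	1.65
kernel_row_number	E3	HY	13.20	1.40
kernel_row_number	E4	CK	12.80	1.03
kernel_row_number	E4	HY	13.20	1.03
kernel_row_number	E5	CK	13.11	1.45
kernel_row_number	E5	HY	13.79	1.03
kernel_row_number	E6	CK	13.71	1.36
kernel_row_number	E6	HY	14.51	1.33
kernel_row_number	Average	CK	13.40	1.37
kernel_row_number	Average	HY	13.75	1.21
kernel_number_per_row	E1	CK	36.00	3.02
kernel_number_per_row	E1	HY	34.60	1.65
kernel_number_per_row	E2	CK	38.70	1.16
kernel_number_per_row	E2	HY	37.20	2.35
kernel_number_per_row	E3	CK	38.70	1.89
kernel_number_per_row	E3	HY	37.30	2.36
kernel_number_per_row	E4	CK	37.20	1.99
kernel_number_per_row	E4	HY	38.40	2.01
kernel_number_per_row	E5	CK	36.69	2.91
kernel_number_per_row	E5	HY	37.76	2.08
kernel_number_per_row	E6	CK	36.46	2.58
kernel_number_per_row	E6	HY	35.20	2.90
kernel_number_per_row	Average	CK	37.29	2.26
kernel_number_per_row	Average	HY	36.74	2.23
ear_weight_g	E1	CK	181.00	22.35
ear_weight_g	E1	HY	204.00	10.75
ear_weight_g	E2	CK	118.93	5.79
ear_weight_g	E2	HY	125.45	6.38
ear_weight_g	E3	CK	211.00	13.70
ear_weight_g	E3	HY	225.00	14.34
ear_weight_g	E4	CK	195.00	13.54
ear_weight_g	E4	HY	216.00	24.13
ear_weight_g	E5	CK	169.67	10.29
ear_weight_g	E5	HY	189.62	14.32
ear_weight_g	E6	CK	201.97	11.62
ear_weight_g	E6	HY	212.35	8.80
ear_weight_g	Average	CK	179.44	12.88
ear_weight_g	Average	HY	195.40	13.12
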