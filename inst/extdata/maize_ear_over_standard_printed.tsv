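# Published per-environment over-standard heterosis percentages (HY over CK)
# for the six ear traits; "Average" rows are the published six-environment
# averages of these percentages.
trait	environment	over_standard_pct
ear_width_mm	E1	3.92
ear_width_mm	E2	3.21
ear_width_mm	E3	3.59
ear_width_mm	E4	6.00
ear_width_mm	E5	8.43
ear_width_mm	E6	8.14
ear_width_mm	Average	5.55
axile_width_mm	E1	8.94
axile_width_mm	E2	1.57
axile_width_mm	E3	5.58
axile_width_mm	E4	3.17
axile_width_mm	E5	2.44
axile_width_mm	E6	7.62
axile_width_mm	Average	4.89
ear_length_cm	E1	0.30
ear_length_cm	E2	2.90
ear_length_cm	E3	-2.98
ear_length_cm	E4	-4.19
ear_length_cm	E5	3.80
ear_length_cm	E6	1.60
ear_length_cm	Average	0.24
kernel_row_number	E1	4.35
kernel_row_number	E2	-1.46
kernel_row_number	E3	-1.40
kernel_row_number	E4	3.13
kernel_row_number	E5	5.20
kernel_row_number	E6	5.85
kernel_row_number	Average	2.61
kernel_number_per_row	E1	-3.80
kernel_number_per_row	E2	-3.80
kernel_number_per_row	E3	-3.61
kernel_number_per_row	E4	3.23
kernel_number_per_row	E5	2.90
kernel_number_per_row	E6	-2.60
kernel_number_per_row	Average	-1.28
ear_weight_g	E1	12.70
ear_weight_g	E2	5.49
ear_weight_g	E3	6.64
ear_weight_g	E4	10.77
ear_weight_g	E5	10.20
ear_weight_g	E6	5.14
ear_weight_g	Average	8.03
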