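k	avg_coverage	avg_length	max_length	n_transcripts	pct_over_1000
19	76.6	421.23	7102	89988	7.54
21	76.6	432.42	6873	83774	8.94
23	76.6	439.55	5759	74336	9.16
25	76.6	417.5	6350	62526	8.24
27	77.8	379.85	5097	47389	6.73
29	86.9	333.96	4441	26733	4.59
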