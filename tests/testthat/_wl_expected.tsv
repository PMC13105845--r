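16.0	0.0	2.0	2.0	2.0	0.0	4.0	8.0	0.0	2.0	0.0	2.0	0.0	0.0	0.0	0.0	0.0	0.0	4.0	2.0
0.0	14.0	2.0	1.0	0.0	9.0	5.0	1.0	6.0	0.0	2.0	1.0	0.0	5.0	0.0	5.0	0.0	1.0	1.0	2.0
2.0	2.0	32.0	4.0	1.0	29.0	8.0	9.0	2.0	12.0	3.0	9.0	4.0	2.0	6.0	11.0	1.0	2.0	8.0	2.0
2.0	1.0	4.0	40.0	3.0	15.0	4.0	12.0	2.0	2.0	6.0	10.0	2.0	2.0	0.0	6.0	4.0	2.0	23.0	15.0
2.0	0.0	1.0	3.0	8.0	0.0	2.0	3.0	0.0	1.0	1.0	2.0	0.0	1.0	0.0	2.0	0.0	0.0	3.0	5.0
0.0	9.0	29.0	15.0	0.0	182.0	18.0	17.0	8.0	18.0	4.0	31.0	24.0	5.0	6.0	24.0	4.0	12.0	29.0	2.0
4.0	5.0	8.0	4.0	2.0	18.0	28.0	9.0	4.0	3.0	2.0	7.0	2.0	5.0	0.0	5.0	1.0	1.0	8.0	4.0
8.0	1.0	9.0	12.0	3.0	17.0	9.0	52.0	2.0	8.0	7.0	10.0	2.0	0.0	2.0	5.0	4.0	2.0	39.0	13.0
0.0	6.0	2.0	2.0	0.0	8.0	4.0	2.0	32.0	0.0	2.0	2.0	0.0	4.0	0.0	6.0	0.0	2.0	2.0	2.0
2.0	0.0	12.0	2.0	1.0	18.0	3.0	8.0	0.0	38.0	4.0	6.0	2.0	0.0	10.0	13.0	0.0	1.0	4.0	1.0
0.0	2.0	3.0	6.0	1.0	4.0	2.0	7.0	2.0	4.0	22.0	2.0	0.0	3.0	2.0	7.0	2.0	0.0	15.0	11.0
2.0	1.0	9.0	10.0	2.0	31.0	7.0	10.0	2.0	6.0	2.0	56.0	2.0	1.0	2.0	11.0	4.0	3.0	16.0	4.0
0.0	0.0	4.0	2.0	0.0	24.0	2.0	2.0	0.0	2.0	0.0	2.0	16.0	0.0	0.0	2.0	0.0	2.0	4.0	0.0
0.0	5.0	2.0	2.0	1.0	5.0	5.0	0.0	4.0	0.0	3.0	1.0	0.0	14.0	0.0	7.0	0.0	0.0	1.0	5.0
0.0	0.0	6.0	0.0	0.0	6.0	0.0	2.0	0.0	10.0	2.0	2.0	0.0	0.0	16.0	6.0	0.0	0.0	0.0	0.0
0.0	5.0	11.0	6.0	2.0	24.0	5.0	5.0	6.0	13.0	7.0	11.0	2.0	7.0	6.0	64.0	0.0	5.0	8.0	8.0
0.0	0.0	1.0	4.0	0.0	4.0	1.0	4.0	0.0	0.0	2.0	4.0	0.0	0.0	0.0	0.0	8.0	0.0	9.0	3.0
0.0	1.0	2.0	2.0	0.0	12.0	1.0	2.0	2.0	1.0	0.0	3.0	2.0	0.0	0.0	5.0	0.0	12.0	4.0	0.0
4.0	1.0	8.0	23.0	3.0	29.0	8.0	39.0	2.0	4.0	15.0	16.0	4.0	1.0	0.0	8.0	9.0	4.0	120.0	29.0
2.0	2.0	2.0	15.0	5.0	2.0	4.0	13.0	2.0	1.0	11.0	4.0	0.0	5.0	0.0	8.0	3.0	0.0	29.0	44.0
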