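chrom	nBins	sizeCM	maxGap
1	623	309.26	12.32
2	324	382.80	34.51
3	450	228.78	9.92
4	415	279.34	20.83
5	381	189.79	5.98
6	141	153.86	7.65
7	291	185.30	13.30
8	253	167.92	5.18
9	307	200.09	13.23
10	120	139.51	13.53
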