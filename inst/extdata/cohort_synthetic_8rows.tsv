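exposure	metabolite_001	age	sex	bmi
1	0.3335	-1.451	0	1.1191
0	0.1615	-1.4434	1	-0.1389
1	0.3944	1.6223	0	0.686
0	0.5089	-0.0248	1	0.1685
0	-0.9533	1.7403	1	-0.3179
1	1.184	0.2167	0	-2.1314
0	-1.2799	-0.7767	0	-0.8129
1	0.3705	-0.4425	1	1.5448
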