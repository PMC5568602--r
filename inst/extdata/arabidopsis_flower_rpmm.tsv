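replicate	transcript_id	Col_0	Kil_0	cv_published	mean_rpmm_published	description
1	AT1G67090.1	9476	9191	1.53	9333.5	Ribulose bisphosphate carboxylase small chain 1A
1	AT5G38410.1	7760	8135	2.36	7947.5	Ribulose bisphosphate carboxylase (small chain) family protein
1	AT5G38430.1	7054	7548	3.38	7301	Ribulose bisphosphate carboxylase (small chain) family protein
1	AT2G39730.1	4051	4343	3.48	4197	Rubisco activase
1	AT5G38420.1	7329	7889	3.68	7609	Ribulose bisphosphate carboxylase (small chain) family protein
2	AT2G39730.1	3906	4323	5.07	4114.5	Rubisco activase
2	AT1G67090.1	8523	9636	6.13	9079.5	Ribulose bisphosphate carboxylase small chain 1A
2	AT1G21310.1	7013	7976	6.42	7494.5	Extensin 3
2	AT5G38410.1	7047	8438	8.98	7742.5	Ribulose bisphosphate carboxylase (small chain) family protein
3	AT5G38420.1	8708	8526	1.06	8617	Ribulose bisphosphate carboxylase (small chain) family protein
3	AT5G38430.1	8424	8169	1.54	8296.5	Ribulose bisphosphate carboxylase (small chain) family protein
3	AT2G39730.1	4365	4524	1.79	4444.5	Rubisco activase
3	AT5G38410.1	9172	8822	1.95	8997	Ribulose bisphosphate carboxylase (small chain) family protein
3	AT1G67090.1	11051	9694	6.54	10372.5	Ribulose bisphosphate carboxylase small chain 1A
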