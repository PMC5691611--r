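il	strain	replicate	start_conc	initial_rate	end_conc	final_rate	final_rate_sd	change_conc	n_flasks
[C4C1Im]Cl	MG1655	ALE1	1.5	0.3	6.2	0.2	0.02	4.7	62
[C4C1Im]Cl	MG1655	ALE2	1.5	0.2	6.2	0.1	0.03	4.7	67
[C4C1Im]Cl	MG1655	ALE3	1.5	0.3	4.9	0.3	0.12	3.4	63
[C4C1Im]Cl	MG1655	ALE4	1.5	0.2	5.6	0.1	0.05	4.1	84
[C4C1Im]Cl	DH1	ALE5	1.5	0.2	4.8	0.2	0.05	3.3	61
[C4C1Im]Cl	DH1	ALE6	1.5	0.2	5.6	0.3	0.08	4.1	72
[C4C1Im]Cl	DH1	ALE7	1.5	0.2	5.6	0.1	0.01	4.1	79
[C4C1Im]Cl	DH1	ALE8	1.5	0.2	4.2	0.2	0.02	2.7	50
[C2C1Im][OAc]	MG1655	ALE9	2	0.2	5.9	0.1	0.00	3.9	86
[C2C1Im][OAc]	MG1655	ALE10	2	0.2	5.9	0.1	0.04	3.9	87
[C2C1Im][OAc]	MG1655	ALE11	2	0.2	6.5	0.2	0.00	4.5	91
[C2C1Im][OAc]	MG1655	ALE12	2	0.2	5.9	0.1	0.01	3.9	92
[C2C1Im][OAc]	DH1	ALE13	1	0.1	4.5	0.1	0.06	3.5	77
[C2C1Im][OAc]	DH1	ALE14	1	0.1	4.5	0.1	0.02	3.5	92
[C2C1Im][OAc]	DH1	ALE15	1	0.2	4.5	0.2	0.01	3.5	79
[C2C1Im][OAc]	DH1	ALE16	1	0.2	5.2	0.2	0.02	4.2	88
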