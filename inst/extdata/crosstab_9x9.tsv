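male_cluster	1	2	3	4	5	6	7	8	9
1	4353	278	10	504	0	0	80	4	0
2	80	530	1064	471	126	141	3032	26	0
3	0	3	0	1	0	0	11	0	0
4	1166	396	42	1009	54	13	860	35	4
5	0	0	0	0	0	0	3	0	0
6	0	0	0	0	0	0	3	0	0
7	16	263	239	519	112	144	5023	34	5
8	41	25	0	111	0	0	46	4	0
9	9	24	2	132	0	1	169	7	0
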