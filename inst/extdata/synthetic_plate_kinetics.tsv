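time_min	A1	A2	A3	B1	B2	B3
0	994.98	1135.11	982.12	1105.72	1096.76	1108.47
5	867.36	982.49	847.14	990.62	1055.81	1083.06
10	786	856.84	778.94	936.96	986.31	1049.79
15	739.79	832.44	720.32	953.19	977.61	995.19
20	704.59	781.82	680.01	927.72	907.77	992.87
25	655.86	716.15	648.08	866.87	879.15	930.22
30	605.35	670.1	619.99	858.74	836.09	843.61
35	581.82	629.07	585.31	780	807.55	864.86
40	547.25	619.22	563.5	708.49	831.49	810.12
45	532.98	589.92	541.41	723.22	682.66	800.23
50	505.75	551.13	503.04	709.82	736.29	716.45
55	495.59	556.82	484.57	651.31	737.02	687.2
60	488.94	510.79	472.95	675.84	624.91	765.84
65	479.19	493.86	427.23	647.47	654.27	675.12
70	449.73	480.7	431.21	608.81	574.98	627.72
75	424.31	469.9	429.46	600.54	615.4	588.18
80	433.89	454.14	426.32	639.6	622.15	596.32
85	411.61	429.38	403.9	545.45	598.08	593.02
90	399.42	414.45	400.21	537.02	536.15	581.95
95	409.46	427.68	364.78	557.79	539.34	524.17
100	388.39	406.39	365.88	567.48	561.67	511.1
105	368.47	385.08	348.96	473.41	509.45	507.66
110	359.01	394.09	357.99	478.23	477.7	461.5
115	334.9	367.11	342.53	492.78	505.36	502.25
120	350.15	368.41	327.69	468.13	424.12	468.62
125	344.44	356.67	322.13	461.79	447.79	392.39
130	309.13	341.92	314.19	453.84	385.87	459.84
135	316.82	332.6	310.75	466.32	435.39	464.77
140	308.91	325.62	287.27	399.09	430.02	456.22
145	306.11	301.5	278.52	395.1	433.09	436.53
150	312.09	311.27	278.77	398.67	418.7	400.89
155	298.43	305.67	256.73	359.42	369.81	363.85
160	278.7	281.02	275.41	368.4	366.25	431.43
165	279.37	295.18	269.26	354.22	309.64	367.62
170	275.33	269.46	227.93	348.71	381.85	298.77
175	255.02	277.82	257.72	305.31	414.49	418.23
180	263.46	291.1	243.33	303.32	318.3	309.9
185	257.75	254.42	272.17	348.59	309.06	362.6
190	249.68	270.98	247.33	308.56	386.86	321.88
195	242.16	246.92	232.76	287.4	292.64	374.13
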