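pair	s_sites	n_sites	ka	ks	omega	selection	time_mya
ABCI7_ABCB28	101.7	312.3	0.0361	0.2692	0.134	Purify selection	8.97
ABCA7_ABCA1	426.3	1430.7	0.1214	0.6921	0.1754	Purify selection	23.07
ABCA7_ABCA10	387.3	1325.7	0.2713	1.1081	0.2449	Purify selection	36.94
ABCA8_ABCA1	637.9	2110.1	0.1567	0.6438	0.2433	Purify selection	21.46
ABCG55_ABCG33	459.5	1457.5	0.0181	0.3379	0.0534	Purify selection	11.26
ABCA8_ABCA10	548.6	1884.4	0.3411	0.718	0.4751	Purify selection	23.93
ABCI3_ABCA10	184.7	634.3	0.2605	0.9483	0.2747	Purify selection	31.61
ABCB36_ABCB4	513.5	1622.5	0.0358	0.3744	0.0955	Purify selection	12.48
ABCC21_ABCC3	833.1	2877.9	0.4073	0.2114	1.9264	Positive selection	7.05
ABCC8_ABCC3	907	2972	0.3718	0.264	1.4083	Positive selection	8.8
ABCG39_ABCG54	998.5	3303.5	0.0407	0.4111	0.0991	Purify selection	13.7
ABCC14_ABCC12	828.4	2879.6	0.4574	0.3221	1.4202	Positive selection	10.74
ABCC14_ABCC10	934.3	2995.7	0.0773	0.421	0.1836	Purify selection	14.03
ABCB18_ABCB27	795.6	2522.4	0.0923	0.5602	0.1647	Purify selection	18.67
ABCC20_ABCC3	1022.8	3318.2	0.0711	0.3866	0.1838	Purify selection	12.89
ABCB13_ABCB12	918	2913	0.0214	0.3618	0.0592	Purify selection	12.06
ABCG21_ABCG10	998.9	3207.1	0.0312	0.3336	0.0935	Purify selection	11.12
ABCG44_ABCG7	357.6	1103.5	0.0806	0.2724	0.2959	Purify selection	9.08
ABCC20_ABCC2	948.6	3050.4	0.1483	0.1105	1.3417	Positive selection	3.68
ABCC8_ABCC2	972.1	3176.9	0.2673	0.7469	0.3578	Purify selection	24.9
ABCC21_ABCC2	946.1	3055.9	0.3096	0.6745	0.459	Purify selection	22.48
ABCB35_ABCB25	854.1	2598.9	0.1366	0.1034	1.3209	Positive selection	3.45
ABCC15_ABCC10	935.2	3144.8	0.3639	0.5253	0.6928	Purify selection	17.51
ABCC12_ABCC10	969	3225	0.299	0.8343	0.3583	Purify selection	27.81
ABCG6_ABCG49	482	1453	0.0674	0.4778	0.1411	Purify selection	15.93
ABCA8_ABCI3	190.6	658.4	0.1729	0.4297	0.4024	Purify selection	14.32
ABCE1_ABCE4	403.6	1336.4	0.0159	0.3465	0.0458	Purify selection	11.55
ABCE1_ABCE6	403.8	1336.2	0.0128	0.3867	0.0332	Purify selection	12.89
ABCG42_ABCG53	477.8	1541.2	0.0167	0.3074	0.0544	Purify selection	10.25
ABCG14_ABCG47	503.7	1587.3	0.1408	0.8319	0.1693	Purify selection	27.73
ABCA1_ABCA10	556	1850	0.3796	0.3834	0.99	Purify selection	12.78
ABCG35_ABCG3	974.6	3264.4	0.0445	0.3155	0.141	Purify selection	10.52
ABCA7_ABCI3	187	650	0.2065	0.4738	0.4358	Purify selection	15.79
ABCC15_ABCC12	1120	3644	0.0265	0.3014	0.088	Purify selection	10.05
ABCC8_ABCC20	904.9	3043.1	0.3938	0.2233	1.7637	Positive selection	7.44
ABCB11_ABCB5	958.6	3031.4	0.0232	0.4174	0.0555	Purify selection	13.91
ABCC8_ABCC21	1000.5	3268.5	0.1138	0.6474	0.1758	Purify selection	21.58
ABCB17_ABCB28	904.7	2851.3	0.0149	0.4701	0.0316	Purify selection	15.67
ABCB14_ABCB6	1006.1	3190.9	0.0231	0.3068	0.0754	Purify selection	10.23
ABCI15_ABCI11	638.6	2133.4	0.0367	0.3204	0.1147	Purify selection	10.68
ABCI16_ABCI4	556.1	1861.9	0.0032	0.2802	0.0115	Purify selection	9.34
ABCI16_ABCI10	557.1	1864	0.0059	0.3252	0.0182	Purify selection	10.84
ABCG2_ABCG13	455.1	1455.9	0.0457	0.2647	0.1725	Purify selection	8.82
ABCE4_ABCE6	419.3	1395.7	0.0072	0.3489	0.0206	Purify selection	11.63
ABCI4_ABCI10	558.7	1865.3	0.0032	0.276	0.0117	Purify selection	9.2
ABCG16_ABCG47	506.8	1587.2	0.0779	0.3979	0.1959	Purify selection	13.26
ABCG15_ABCG47	324.9	1016.1	0.2803	0.1506	1.8615	Positive selection	5.02
ABCG17_ABCG47	420.4	1373.6	0.3868	0.2192	1.7644	Positive selection	7.31
ABCA9_ABCI3	170.8	552.2	0.4139	0.5472	0.7564	Purify selection	18.24
ABCB17_ABCI7	101.8	312.2	0.0361	0.2976	0.1213	Purify selection	9.92
ABCA6_ABCI3	190.8	649.2	0.1545	0.6303	0.2452	Purify selection	21.01
ABCI29_ABCI8	203.3	675.7	0.0279	0.3872	0.072	Purify selection	12.91
ABCF6_ABCF4	405.4	1346.6	0.0617	0.4685	0.1317	Purify selection	15.62
ABCG41_ABCI27	86.6	309.4	0.0364	0.4439	0.0821	Purify selection	14.8
ABCA6_ABCA1	656.7	2169.3	0.0777	0.3726	0.2086	Purify selection	12.42
ABCA9_ABCA1	459.7	1547.3	0.5582	0.9212	0.606	Purify selection	30.71
ABCA6_ABCA10	585.3	1934.7	0.2449	1.1391	0.2149	Purify selection	37.97
ABCA9_ABCA10	441	1446	0.6087	0.6633	0.9177	Purify selection	22.11
ABCG57_ABCG16	506.5	1581.6	0.0697	0.3955	0.1764	Purify selection	13.18
ABCG57_ABCG15	350.3	1068.7	0.1476	0.6815	0.2165	Purify selection	22.72
ABCG57_ABCG17	467.6	1476.4	0.2053	1.2659	0.1622	Purify selection	42.2
ABCC7_ABCC1	918.1	2984.9	0.1512	0.1284	1.1774	Positive selection	4.28
ABCB18_ABCB26	436.6	1384.4	0.2332	0.1448	1.6106	Positive selection	4.83
ABCG22_ABCG9	983.5	3297.5	0.0375	0.4045	0.0926	Purify selection	13.48
ABCB2_ABCB8	890.4	2802.6	0.0566	0.3556	0.1592	Purify selection	11.85
ABCG28_ABCG23	972.9	3257.1	0.0592	0.4121	0.1437	Purify selection	13.74
ABCG27_ABCG23	977.1	3279.9	0.0649	0.3697	0.1755	Purify selection	12.32
ABCE2_ABCE3	416.3	1392.7	0.0879	0.6704	0.1311	Purify selection	22.35
ABCG50_ABCG49	488.3	1455.7	0.0566	0.4861	0.1164	Purify selection	16.2
ABCG45_ABCG20	485.2	1554.8	0.0363	0.4193	0.0867	Purify selection	13.98
ABCG57_ABCG47	513.3	1598.7	0.0484	0.4063	0.1192	Purify selection	13.54
ABCG40_ABCG54	997.6	3304.4	0.0432	0.4119	0.105	Purify selection	13.73
ABCG50_ABCG6	493.9	1474.1	0.0617	0.5136	0.1202	Purify selection	17.12
ABCG61_ABCG4	550	1697	0.0279	0.3461	0.0806	Purify selection	11.54
ABCG57_ABCG14	480	1551	0.22	0.3336	0.6596	Purify selection	11.12
ABCI26_ABCI18	554.5	1872.5	0.0322	0.3497	0.092	Purify selection	11.66
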