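gene	RC1	RC2	RC3	RM1	RM2	RM3	HC1	HC2	HC3
G01	10.147	7.584	8.288	30.023	41.585	39.397	24.71	31.516	31.039
G02	58.041	47.013	60.129	66.074	66.903	76.692	49.591	54.872	53.15
G03	136.334	124.241	146.018	141.534	129.967	107.56	130.78	118.521	131.69
G04	17.852	19.753	14.104	20.393	15.671	22.039	13.464	15.923	15.022
G05	274.564	355.573	201.97	225.659	208.081	228.017	256	238.36	283.656
G06	31.407	29.692	34.487	40.113	35.58	32.582	29.713	38.8	41.013
G07	83.17	61.223	55.599	67.837	61.649	59.466	57.56	58.892	53.892
G08	125.888	94.288	164.392	153.277	123.983	125.279	90.134	118.768	138.525
G09	22.706	17.328	14.846	18.765	18.804	16.53	12.942	18.051	16.235
G10	253.177	229.126	286.82	290.018	295.088	261.379	264.111	213.191	299
G11	226.914	195.904	191.341	26.704	40.729	31.867	35.31	31.779	30.76
G12	20.706	15.736	12.159	62.988	58.933	65.209	58.77	48.908	73.977
G13	350.434	533.373	585.693	142.617	143.31	117.702	128	156.715	94.615
G14	15.242	14.4	17.889	13.567	20.365	14.662	19.441	15.263	21.437
G15	250.211	279.364	259.934	232.97	211.132	192.005	328.557	236.058	297.346
G16	35.728	23.769	33.568	35.383	27.569	29.94	26.465	25.813	31.168
G17	60.927	55.87	72.004	73.11	52.6	58.566	62.726	63.911	49.797
G18	80.784	110.431	129.967	138.717	99.388	204.364	157.586	111.43	143.112
G19	10.483	10.527	9.527	13.728	16.223	12.632	14.754	14.591	17.4
G20	321.795	257.602	268.914	211.571	286.621	262.105	253.704	320.016	255.645
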