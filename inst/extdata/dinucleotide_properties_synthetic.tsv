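token	P01	P02	P03	P04	P05	P06	P07	P08	P09	P10	P11	P12	P13	P14	P15
AA	1.034	1.592	-0.385	1.636	-0.894	-0.163	-0.027	-0.991	0.347	1.383	-0.566	-0.247	-0.11	0.505	-0.586
AC	0.773	1.439	0.426	1.077	-1.503	0.791	-0.242	-1.76	0.034	1.406	-0.832	0.166	-0.27	-0.99	-0.814
AG	0.678	-0.518	1.587	-2.821	0.146	-0.642	-0.354	0.756	0.598	-1.104	0.752	0.247	-0.065	1.145	1.244
AT	0.14	-0.006	1.129	1.119	0.257	-2.762	-0.168	0.351	-0.457	-0.692	-0.328	1.015	0.759	-2.189	-0.984
AN	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
CA	1.415	0.782	-0.092	-1.65	1.565	-0.02	-1.837	1.982	-0.629	-0.299	0.024	-1.109	-0.772	-0.923	0.99
CC	-0.977	-0.859	-2.189	1.122	-0.293	0.351	1.293	-0.256	1.038	-0.63	0.978	1.274	0.228	1.009	-0.34
CG	0.375	1.42	-1.037	-0.314	-0.078	-0.694	0.148	0.513	0.906	0.017	-0.924	-0.164	0.523	0.309	-0.567
CT	-0.619	-1.062	1.031	-0.85	-1.022	-1.796	2.066	-2.061	-1.473	0.056	-1.1	-0.822	-1.016	0.25	-1.238
CN	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
GA	0.706	-0.858	1.403	1.007	0.426	2.562	0.557	-1.917	-1.201	0.765	-0.657	1.539	-2.341	1.684	-0.895
GC	-0.789	-1.363	0.221	0.565	0.679	-0.606	0.181	0.165	0.52	0.683	-0.058	-0.824	-1.39	-2.122	-1.216
GG	2.209	1.403	-0.92	-1.133	-0.846	-0.546	0.407	1.309	1.228	0.35	1.094	0.088	-0.401	-0.745	-0.413
GT	0.592	-0.362	-0.471	0.189	1.178	-0.833	0.618	-1.336	0.606	0.347	0.417	0.438	0.574	-0.088	0.099
GN	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
TA	0.916	-1.999	-1.131	-0.829	0.439	-0.001	0.368	0.605	0.581	-2.312	0.463	-1.291	0.161	-0.507	1.327
TC	1.03	0.174	1.232	-0.632	0.423	0.001	0.819	-0.262	0.084	1.302	-0.434	0.945	0.561	-0.702	0.628
TG	-0.775	0.724	2.073	-0.202	-0.919	0.885	0.241	-1.037	0.655	-1.199	-1.099	-0.309	-0.057	0.316	-0.624
TT	1.144	1.499	1.138	0.305	-0.666	-0.111	1.188	0.841	-0.227	-0.111	-0.292	0.236	0.113	-0.122	1.224
TN	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
NA	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
NC	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
NG	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
NT	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
NN	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
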