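token	P01	P02	P03	P04	P05	P06	P07	P08	P09	P10	P11
AAA	-0.08	-1.016	-0.095	1.391	-0.366	-0.756	-0.551	-0.398	-0.42	-1.173	0.065
AAC	-0.694	-0.118	-3.122	-0.371	-1.777	0.264	-0.443	0.738	0.888	-0.515	-0.335
AAG	-0.859	-1.424	0.763	-3.227	-1.231	-1.654	-1.07	-0.091	1.147	1.039	1.566
AAT	1.501	-0.856	1.562	-1.454	0.759	-0.713	0.513	0.667	0.817	1.413	1.568
AAN	0	0	0	0	0	0	0	0	0	0	0
ACA	0.098	0.915	0.006	-0.342	1.883	-1.344	-1.787	2.662	-0.86	0.744	-1.735
ACC	-1.424	0.6	-1.529	0.539	-1.94	1.401	-0.514	1.97	0.283	-0.389	0.826
ACG	-0.959	0.16	2.373	1.626	-1.187	0.713	-0.587	-0.629	1.745	0.398	-0.291
ACT	-0.515	-0.936	1.769	3.114	0.452	0.727	-0.477	2.824	-0.722	-0.767	0.511
ACN	0	0	0	0	0	0	0	0	0	0	0
AGA	-0.683	0.98	-0.912	-1.77	1.022	-0.141	0.638	-0.694	-1.363	0.686	-1.193
AGC	0.684	1.185	-0.169	-0.212	1.073	0.219	0.527	0.833	-1.433	-1.06	-1.914
AGG	-2.289	-1.244	0.398	-0.221	0.931	0.567	-1.003	0.529	1.184	0.29	0.364
AGT	-0.102	-0.438	1.947	0.012	1.955	-0.409	0.83	-0.617	-0.924	0.064	-0.45
AGN	0	0	0	0	0	0	0	0	0	0	0
ATA	0.591	-0.523	0.653	0.01	0.14	-1.583	-1.035	0.614	-0.646	0.791	-0.353
ATC	0.801	0.668	0.338	1.164	1.615	0.752	-2.015	-1.005	-1.142	-2.357	0.756
ATG	1.233	-2.129	-1.419	0.429	-0.364	-1.672	-0.769	-0.852	-0.189	-0.326	0.135
ATT	-0.309	-1.953	1.448	0.198	-1.492	-0.295	0.417	-2.067	0.223	-0.5	-0.143
ATN	0	0	0	0	0	0	0	0	0	0	0
ANA	0	0	0	0	0	0	0	0	0	0	0
ANC	0	0	0	0	0	0	0	0	0	0	0
ANG	0	0	0	0	0	0	0	0	0	0	0
ANT	0	0	0	0	0	0	0	0	0	0	0
ANN	0	0	0	0	0	0	0	0	0	0	0
CAA	1.921	0.886	-0.802	-0.76	-0.273	0.119	0.644	-0.305	0.609	-1.019	-1.114
CAC	0.543	1.319	-0.664	-0.069	1.223	1.585	-0.088	-0.042	1	1.032	0.88
CAG	-0.864	1.836	-0.82	-1.678	1.358	-1.273	-1.012	-0.466	0.649	-0.278	-1.421
CAT	0.416	-0.796	-0.183	-1.091	0.146	0.883	1.25	0.412	-0.416	-1.91	-0.17
CAN	0	0	0	0	0	0	0	0	0	0	0
CCA	0.145	-0.41	0.136	-0.392	0.074	-0.993	2.182	-0.963	-0.999	0.263	0.289
CCC	-1.184	-0.819	2.351	0.41	-0.071	-0.9	-0.843	0.736	-0.02	0.701	-0.588
CCG	1.398	2.23	0.177	-2.25	0.645	-0.508	0.37	-1.814	-0.795	-0.494	-0.743
CCT	-0.512	1.484	-0.32	-0.01	0.358	-1.923	2.319	-1.254	0.427	0.714	-1.598
CCN	0	0	0	0	0	0	0	0	0	0	0
CGA	-0.252	1.26	0.278	-0.035	-0.353	1.088	-0.021	-1.379	-0.178	0.746	-0.682
CGC	0.214	-0.202	1.239	0.123	1.365	-0.66	0.1	1.819	-0.194	-1.091	0.813
CGG	0.867	-1.024	-0.092	0.792	0.8	1.028	-1.105	0.382	0.069	-0.06	0.979
CGT	-0.21	0.183	1.163	1.572	-0.162	-0.209	0.527	1.372	0.371	-0.096	-1.249
CGN	0	0	0	0	0	0	0	0	0	0	0
CTA	0.5	0.204	-0.441	-1.389	0.001	0.529	-0.48	1.733	-0.293	0.274	1.576
CTC	-1.661	-0.861	-0.559	1.327	0.56	-0.316	1.514	-0.704	-0.067	1.533	-0.803
CTG	0.472	1.271	-0.747	-1.749	-0.891	1.959	-2.176	1.232	0.788	-1.124	-1.074
CTT	-1.327	-0.255	0.28	0.278	-1.129	-1.552	1.174	-1.746	1.599	-0.903	-0.678
CTN	0	0	0	0	0	0	0	0	0	0	0
CNA	0	0	0	0	0	0	0	0	0	0	0
CNC	0	0	0	0	0	0	0	0	0	0	0
CNG	0	0	0	0	0	0	0	0	0	0	0
CNT	0	0	0	0	0	0	0	0	0	0	0
CNN	0	0	0	0	0	0	0	0	0	0	0
GAA	0.564	-0.728	1.451	-0.46	1.047	-1.337	0.139	0.38	0.05	0.27	-0.271
GAC	0.017	-0.324	0.644	-1.639	0.425	-0.634	0.595	1.978	-0.966	-1.51	-1.062
GAG	0.93	-1.135	-1.405	-0.228	0.35	-0.552	0.864	0.524	-0.092	-0.917	-0.793
GAT	-1.997	0.449	-1.391	-1.399	-0.338	-0.282	0.56	0.291	-1.682	0.368	0.808
GAN	0	0	0	0	0	0	0	0	0	0	0
GCA	1.661	0.534	0.178	1.445	-1.167	-0.327	0.383	-0.419	-2.339	-0.009	-0.378
GCC	-2.167	0.8	0.989	-1.698	0.895	-1.18	1.519	-1.323	1.18	-0.265	-0.449
GCG	0.614	-0.564	0.735	0.081	-1.889	0.05	1.426	-0.047	0.456	0.302	-0.917
GCT	-1.696	0.518	0.61	-1.598	-0.942	-1.385	0.004	0.188	-1.381	-1.068	0.738
GCN	0	0	0	0	0	0	0	0	0	0	0
GGA	-0.811	1.378	-1.325	-0.582	1.137	0.764	-1.62	0.239	-0.532	1.573	-1.669
GGC	0.078	1.609	-1.848	1.096	1.668	-2.094	0.374	-0.427	-0.89	-0.201	1.258
GGG	-0.405	-0.552	-0.401	0.242	-0.106	-2.068	-0.582	-1.038	-2.013	1.452	1.497
GGT	-2.96	1.163	-0.874	-0.362	-0.006	0.084	0.111	-0.077	-0.175	-1.51	1.2
GGN	0	0	0	0	0	0	0	0	0	0	0
GTA	-0.926	0.057	1.245	1.2	-0.929	0.796	0.488	0.41	-0.381	0.874	1.12
GTC	0.6	0.341	2.102	0.113	-0.127	0.243	0.537	1.438	-0.464	-0.3	1.852
GTG	-1.59	1.026	0.672	0.612	0.242	-0.136	-0.842	-0.776	-0.846	-0.516	1.07
GTT	-0.019	-0.334	-0.304	0.561	-1.935	0.254	-0.618	0.999	-1.159	-1.428	1.597
GTN	0	0	0	0	0	0	0	0	0	0	0
GNA	0	0	0	0	0	0	0	0	0	0	0
GNC	0	0	0	0	0	0	0	0	0	0	0
GNG	0	0	0	0	0	0	0	0	0	0	0
GNT	0	0	0	0	0	0	0	0	0	0	0
GNN	0	0	0	0	0	0	0	0	0	0	0
TAA	0.458	0.329	-1.234	-1.403	0.773	-0.3	2.104	-1.041	-0.824	-2.19	-2.624
TAC	-2.852	-0.484	0.08	1.049	0.048	-0.891	0.333	-0.261	0.323	-0.358	-0.387
TAG	0.209	1.116	-0.078	-0.7	0.813	1.336	-0.539	0.16	-1.142	0.04	1.323
TAT	1.439	-0.006	-0.113	-0.076	-0.804	0.938	0.249	0.766	0.509	2.416	0.966
TAN	0	0	0	0	0	0	0	0	0	0	0
TCA	1.736	2.192	-0.447	-0.143	-1.254	0.181	0.613	0.438	0.64	-0.421	-1.102
TCC	-1.115	0.933	1.29	-0.667	0.229	-0.545	-2.367	-0.227	0.537	1.016	-0.316
TCG	-1.528	-0.24	-1.118	0.137	1.203	0.709	0.382	-0.376	-0.215	-0.94	-1.182
TCT	-0.996	-0.891	-0.21	-0.294	0.435	0.292	0.329	-1.316	-0.533	1.217	-0.749
TCN	0	0	0	0	0	0	0	0	0	0	0
TGA	1.695	-0.361	0.293	-1.479	0.1	1.03	0.526	0.89	-0.496	-2.615	0.164
TGC	0.06	-0.447	-0.247	0.188	2.09	0.572	0.096	1.104	0.358	0.221	0.825
TGG	0.479	-1.065	0.666	-0.569	-0.095	0.5	0.303	-1.759	-0.48	-0.02	0.4
TGT	1.704	0.252	-1.714	-0.133	-0.688	-0.569	0.841	1.964	0.335	-1.924	-0.003
TGN	0	0	0	0	0	0	0	0	0	0	0
TTA	1.444	2.126	0.296	-1.245	-0.148	0.197	-0.136	-0.039	0.972	1.367	-0.77
TTC	0.265	0.44	1.101	1.615	-0.443	1.173	0.56	-0.365	-0.44	-0.267	0.658
TTG	1.159	0.809	-1.237	-0.105	-1.258	-0.363	-0.137	-0.45	1.853	-0.616	-0.648
TTT	0.427	-0.554	0.115	0.414	-0.141	-0.274	-0.313	1.408	0.014	-0.269	2.252
TTN	0	0	0	0	0	0	0	0	0	0	0
TNA	0	0	0	0	0	0	0	0	0	0	0
TNC	0	0	0	0	0	0	0	0	0	0	0
TNG	0	0	0	0	0	0	0	0	0	0	0
TNT	0	0	0	0	0	0	0	0	0	0	0
TNN	0	0	0	0	0	0	0	0	0	0	0
NAA	0	0	0	0	0	0	0	0	0	0	0
NAC	0	0	0	0	0	0	0	0	0	0	0
NAG	0	0	0	0	0	0	0	0	0	0	0
NAT	0	0	0	0	0	0	0	0	0	0	0
NAN	0	0	0	0	0	0	0	0	0	0	0
NCA	0	0	0	0	0	0	0	0	0	0	0
NCC	0	0	0	0	0	0	0	0	0	0	0
NCG	0	0	0	0	0	0	0	0	0	0	0
NCT	0	0	0	0	0	0	0	0	0	0	0
NCN	0	0	0	0	0	0	0	0	0	0	0
NGA	0	0	0	0	0	0	0	0	0	0	0
NGC	0	0	0	0	0	0	0	0	0	0	0
NGG	0	0	0	0	0	0	0	0	0	0	0
NGT	0	0	0	0	0	0	0	0	0	0	0
NGN	0	0	0	0	0	0	0	0	0	0	0
NTA	0	0	0	0	0	0	0	0	0	0	0
NTC	0	0	0	0	0	0	0	0	0	0	0
NTG	0	0	0	0	0	0	0	0	0	0	0
NTT	0	0	0	0	0	0	0	0	0	0	0
NTN	0	0	0	0	0	0	0	0	0	0	0
NNA	0	0	0	0	0	0	0	0	0	0	0
NNC	0	0	0	0	0	0	0	0	0	0	0
NNG	0	0	0	0	0	0	0	0	0	0	0
NNT	0	0	0	0	0	0	0	0	0	0	0
NNN	0	0	0	0	0	0	0	0	0	0	0
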