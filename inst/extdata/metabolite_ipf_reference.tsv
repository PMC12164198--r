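trait_label	category	ivw_or	ivw_or_low	ivw_or_high	ivw_p	ivw_significant	ivw_sign	egger_lnor	egger_p	wm_lnor	wm_p	presso_lnor	presso_p	q_ivw	q_ivw_df	q_ivw_p	q_egger	q_egger_df	q_egger_p	egger_intercept	egger_intercept_se	egger_intercept_p	presso_rss	presso_global_p	r2_exposure	r2_outcome	steiger_direction	steiger_p
2-Aminobutyrate	Amino acid	NA	NA	NA	NA	TRUE	1	2.73	0.2340	1.39	0.2105	1.82	0.0048	30.112	44	0.945	29.930	43	0.935	-0.010	0.023	0.672	31.444	0.939	0.1466	1.83e-04	TRUE	1.81e-235
Alpha-hydroxyisovalerate	Amino acid	3.063	1.066	8.804	0.038	TRUE	1	-0.69	0.6595	0.42	0.5968	1.12	0.0538	13.648	14	0.476	12.058	13	0.523	0.056	0.044	0.230	16.554	0.444	0.0910	9.07e-05	TRUE	1.05e-119
Glucose	Carbohydrate	NA	NA	NA	NA	TRUE	1	1.98	0.3034	1.35	0.3351	1.92	0.0253	29.455	36	0.772	29.453	35	0.733	-0.001	0.020	0.970	30.999	0.799	0.1505	1.71e-04	TRUE	5.02e-224
Alpha-ketoglutarate	Energy	2.888	1.044	7.987	0.041	TRUE	1	1.80	0.1065	1.46	0.0700	1.06	0.0378	13.022	16	0.671	12.361	15	0.651	-0.022	0.027	0.429	14.083	0.731	0.0883	8.68e-05	TRUE	3.03e-101
Nonadecanoate (19:0)	Lipid	NA	NA	NA	NA	TRUE	1	2.38	0.1019	1.47	0.1435	1.65	0.0147	10.459	15	0.790	10.070	14	0.757	-0.018	0.030	0.543	11.769	0.798	0.0829	7.96e-05	TRUE	1.41e-105
Taurocholate	Lipid	1.522	1.000	2.314	0.050	TRUE	1	0.30	0.4192	0.56	0.0904	0.42	0.0629	14.335	15	0.500	14.176	14	0.437	0.010	0.025	0.699	16.715	0.528	0.2139	9.19e-05	TRUE	1.55e-147
Octanoylcarnitine	Lipid	0.261	0.103	0.662	0.005	TRUE	-1	-0.70	0.4315	-0.76	0.2518	-1.34	0.0121	17.460	16	0.356	16.569	15	0.345	-0.022	0.025	0.383	23.187	0.313	0.1089	1.32e-04	TRUE	4.35e-171
Epiandrosterone sulfate	Lipid	0.472	0.298	0.745	0.001	TRUE	-1	-0.68	0.0738	-0.70	0.0323	-0.75	0.0073	13.581	12	0.328	13.488	11	0.263	-0.007	0.027	0.788	19.490	0.347	0.1233	1.28e-04	TRUE	1.18e-181
1-Linoleoylglycerophosphocholine	Lipid	0.146	0.024	0.901	0.038	TRUE	-1	-3.47	0.2030	-0.85	0.5071	-1.93	0.0227	9.174	14	0.820	8.765	13	0.790	0.029	0.045	0.534	11.035	0.778	0.0725	6.80e-05	TRUE	3.50e-96
Dihomo-linolenate (20:3n3 or n6)	Lipid	0.167	0.041	0.677	0.012	TRUE	-1	-0.68	0.7571	-1.44	0.1679	-1.79	0.0201	22.865	22	0.409	22.541	21	0.369	-0.021	0.038	0.588	24.927	0.440	0.0979	1.48e-04	TRUE	4.00e-142
n-Butyl oleate	Lipid	NA	NA	NA	NA	TRUE	1	4.10	0.1058	3.36	0.0049	2.12	0.0315	8.480	9	0.487	7.577	8	0.476	-0.044	0.046	0.370	10.527	0.501	0.0505	7.36e-05	TRUE	4.93e-45
Palmitoyl sphingomyelin	Lipid	0.196	0.041	0.938	0.041	TRUE	-1	3.62	0.2592	-1.19	0.3100	-1.63	0.0291	35.688	46	0.864	38.619	47	0.803	-0.051	0.030	0.094	40.314	0.822	0.1503	2.16e-04	TRUE	8.10e-240
Pyroglutamylglycine	Peptide	2.737	1.013	7.397	0.047	TRUE	1	0.98	0.5980	1.05	0.1043	1.00	0.0727	1.599	3	0.660	1.599	2	0.450	0.002	0.092	0.987	3.064	0.682	0.0793	2.80e-05	TRUE	3.25e-22
1,7-Dimethylurate	Xenobiotics	2.545	1.127	5.745	0.025	TRUE	1	0.90	0.2557	1.03	0.1039	0.93	0.0075	5.197	11	0.921	5.194	10	0.878	0.002	0.033	0.956	6.083	0.927	0.0951	5.18e-05	TRUE	3.30e-95
X-10810	Unknown	NA	NA	NA	NA	TRUE	-1	-0.81	0.2898	-1.13	0.1282	-1.12	0.0110	8.479	15	0.903	8.149	14	0.881	-0.013	0.022	0.575	8.780	0.935	0.0653	6.68e-05	TRUE	5.11e-88
X-11491	Unknown	NA	NA	NA	NA	TRUE	1	0.56	0.4049	0.40	0.3576	0.68	0.0569	12.463	12	0.409	12.414	11	0.333	0.006	0.030	0.840	15.115	0.421	0.0956	8.62e-05	TRUE	5.02e-113
X-11850	Unknown	NA	NA	NA	NA	TRUE	1	0.70	0.1397	0.50	0.1016	0.54	0.0246	3.603	6	0.730	3.359	5	0.645	-0.018	0.037	0.643	4.491	0.794	0.0460	4.52e-05	TRUE	3.24e-41
X-11852	Unknown	NA	NA	NA	NA	TRUE	-1	-0.91	0.0296	-0.38	0.2118	-0.45	0.0632	7.386	8	0.496	4.107	7	0.767	0.060	0.033	0.113	12.259	0.410	0.0995	5.90e-05	TRUE	6.42e-53
X-12644	Unknown	NA	NA	NA	NA	TRUE	-1	-2.17	0.0874	-1.84	0.0173	-1.11	0.0584	25.789	23	0.311	24.709	22	0.311	0.024	0.025	0.337	28.031	0.340	0.0981	1.53e-04	TRUE	1.14e-139
X-12786	Unknown	NA	NA	NA	NA	TRUE	-1	-0.98	0.3254	-1.02	0.1660	-1.22	0.0129	5.887	10	0.825	5.797	9	0.760	-0.009	0.030	0.771	6.748	0.859	0.0618	5.69e-05	TRUE	5.35e-70
X-13548	Unknown	NA	NA	NA	NA	TRUE	1	3.13	0.1746	1.15	0.3099	1.58	0.0373	36.737	42	0.701	36.209	41	0.683	-0.017	0.023	0.471	38.748	0.676	0.1940	2.06e-04	TRUE	3.93e-244
X-13671	Unknown	NA	NA	NA	NA	TRUE	-1	-0.40	0.9242	-2.04	0.1420	-3.14	0.0042	11.241	14	0.667	10.763	13	0.631	-0.037	0.054	0.502	12.765	0.712	0.0512	1.04e-04	TRUE	5.93e-72
X-14745	Unknown	NA	NA	NA	NA	TRUE	-1	-4.19	0.4159	-1.25	0.2522	-1.60	0.0720	11.723	11	0.385	11.400	10	0.327	0.058	0.109	0.606	13.737	0.426	0.0491	8.05e-05	TRUE	2.44e-54
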