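oligo	PC01	PC02	PC03	PC04	PC05	PC06	PC07	PC08	PC09	PC10	PC11	PC12	PC13	PC14	PC15	PC16	PC17	PC18	PC19	PC20	PC21	PC22	PC23	PC24	PC25	PC26	PC27	PC28	PC29	PC30	PC31	PC32	PC33	PC34	PC35	PC36	PC37	PC38
AA	-0.0038	1.7675	0.4851	-0.8163	0.0111	-1.6208	-0.5946	1.4994	0.7853	-0.8441	-0.355	0.1358	-1.1886	-0.5771	-2.1148	-1.0729	-0.7627	-1.0323	1.1491	0.272	0.5926	0.124	0.0202	-0.9106	-0.755	0.5504	-0.0805	-1.966	-0.1475	-1.0633	0.438	0.761	-1.3738	1.1452	0.9665	-2.5441	0.9128	-1.2972
AC	0.5232	0.3331	-0.5855	0.161	-1.5241	-0.5846	-0.8362	0.486	-1.046	-0.6015	0.509	0.8699	0.1043	0.1761	-1.0605	0.8105	-1.1312	1.8335	-0.0842	1.6136	0.5612	-0.5638	-0.1831	0.6195	-0.7472	-0.2743	0.2185	-0.318	0.0114	-1.7519	-0.5198	2.63	0.2817	1.5981	0.812	-0.0789	-0.7358	-0.0637
AG	0.9692	0.6963	-0.4406	0.3649	0.6034	-0.8734	0.1574	-0.1909	-2.8386	1.3701	-0.3539	0.6751	0.4169	1.9007	0.2117	-0.0115	-0.0698	0.078	-1.7623	-1.0349	-0.1236	1.7051	0.898	0.5515	0.6641	0.1763	0.9159	-1.9492	-0.1151	1.0284	0.3295	0.8106	0.5003	0.5596	1.2679	-0.3622	-1.2718	-0.5153
AT	0.2559	0.075	-0.6732	-0.0046	0.2876	-1.2368	0.1195	-0.9499	0.705	-1.4715	-0.1072	0.0746	0.0711	-1.306	-0.9693	1.1041	0.6862	0.9368	0.4383	1.2717	0.8012	-0.2475	-0.8535	-1.2015	-0.5953	0.8997	0.2683	0.877	-0.0559	0.9033	-0.3028	-1.6356	-0.8299	-1.2275	-0.8666	-1.1339	0.4404	0.5703
CA	0.5214	0.6061	-0.3201	-0.9338	0.7787	0.5536	0.2577	0.8332	1.0558	0.3746	-0.9616	1.7272	0.43	1.2722	-0.047	-0.4104	0.8387	-0.674	-0.6474	-1.2027	-0.3369	-0.6598	-0.5272	0.7295	1.0405	0.5131	0.5653	0.4505	0.3522	-0.1598	-0.8232	-1.0256	0.5278	0.2518	-1.2804	-0.2743	1.0816	-0.437
CC	0.5372	-0.3584	-1.1827	1.3402	-1.9587	1.62	0.3499	-0.5687	0.27	-0.4964	1.2891	-0.9886	0.6454	0.4027	-0.5027	-0.7057	0.9052	1.7935	-0.2304	0.106	1.4364	0.5157	-0.166	0.2546	0.4607	0.7957	-1.0589	-0.9382	0.7187	-0.7715	-1.2728	0.7697	-0.2017	0.7653	0.2233	0.1765	-0.7978	0.1714
CG	1.1458	0.3739	-0.024	0.8417	0.3959	1.1527	0.0788	-0.5275	-1.0848	-0.9716	1.5379	0.2098	0.427	0.1163	0.2651	2.288	0.2858	0.9013	-0.0046	-0.5831	-0.3859	0.268	-0.4421	1.2829	0.4583	0.7569	-0.8468	1.2325	1.0102	-1.1375	1.2696	-1.1997	-0.536	1.3426	-1.1589	-0.9429	1.1468	0.5373
CT	0.3573	-0.6656	0.5981	-0.7466	-0.8033	-2.4755	-0.4382	-2.4322	-1.2094	1.6591	-1.2595	-0.0789	1.1087	-1.4279	0.7134	1.8608	1.5509	0.92	0.176	1.0608	-2.2911	-1.0682	0.1444	-1.5533	-0.278	0.8661	-1.0356	-1.0659	-0.294	0.3422	0.352	-1.8372	-0.1318	-0.1236	0.1251	-0.0971	0.1676	1.3974
GA	-1.3097	-0.252	0.3637	1.3472	0.0678	0.4376	0.4373	-0.5237	1.5161	-1.6682	0.7512	-2.8829	2.568	-0.0062	0.0682	-0.8864	-0.0825	-0.3026	1.0084	1.1606	-0.7025	0.1961	-0.4348	0.0488	0.1209	-0.2943	1.9346	-0.1447	0.4287	1.7209	-0.1466	-0.5125	0.76	0.1304	-0.5771	-0.9687	-0.0364	0.5923
GC	0.1462	-1.1545	0.6741	0.5758	-0.5657	-0.7992	0.4714	0.7502	1.3926	0.302	-0.1351	0.501	0.0447	-0.7236	-0.9911	-0.5955	0.2619	2.839	0.3018	-0.151	-0.3497	-0.1591	1.0206	0.8989	0.6619	-0.1169	0.296	0.0628	-0.5983	0.1535	1.9159	-0.0611	-0.3296	-1.4114	-0.173	-0.0663	-1.5737	1.0262
GG	0.348	-1.1288	-1.7421	-1.2414	0.2152	-0.6367	-0.0437	1.0245	-1.706	0.8613	-0.0552	-0.1202	-2.3623	-0.0306	0.8971	-1.0311	0.2637	-0.3802	-0.6283	-0.3171	-0.8949	0.273	1.048	-0.4693	-0.7315	-1.1628	-1.2741	0.4131	-0.4063	0.9119	-0.7479	0.0672	0.0787	-0.0534	0.8659	-1.181	-2.1035	0.1197
GT	1.0902	0.6691	-1.2027	0.526	-0.1107	-1.4347	1.1076	-0.6059	1.8373	-0.554	1.2232	1.6196	0.289	0.239	0.5643	0.3781	-0.3198	-0.6061	-1.0595	-0.6986	-0.2844	-0.3478	0.2843	-0.4528	-1.1081	-1.2003	-0.7425	-1.0388	0.9274	0.7952	-0.1681	0.1966	-1.5224	1.3855	1.8224	-1.2136	-2.1342	-0.7406
TA	-3.3229	2.1447	2.4203	1.2007	0.8929	-1.743	-0.8514	-0.4576	-0.6018	0.9205	0.4028	-0.4436	1.3563	-1.1326	-1.3905	0.4587	1.2411	-0.9645	-0.9482	-0.9469	-0.0868	0.8192	0.364	0.8431	-1.4126	1.2183	-0.1879	0.3246	0.3035	0.6428	-0.6707	0.1551	-0.8596	1.2938	-1.0047	-0.6945	1.0642	1.1852
TC	1.0563	0.6204	0.0542	-1.4149	-0.4419	-0.955	-0.6651	0.6618	0.2097	0.6614	-0.2901	0.6842	0.1858	0.4103	-0.278	0.3748	0.6823	0.8625	0.2318	0.2242	1.5567	-1.0214	-1.2822	-1.0573	0.9306	1.4922	0.0921	0.4787	-0.7566	0.5416	-0.6427	2.2256	1.8902	0.169	0.0461	0.947	-0.1316	1.1218
TG	-1.3466	0.2029	0.6406	-0.6096	-1.4647	-2.1296	0.2892	-0.1268	0.7787	0.1349	0.4354	-2.0902	0.0239	0.7756	-0.8015	0.8529	-0.11	-0.7191	0.1349	0.2831	-0.8131	2.1746	-0.322	-0.5191	-1.1541	-1.3862	0.6013	-0.3161	0.7352	-1.2161	1.0834	-0.0437	0.9961	-1.5114	0.3427	-0.3473	0.3171	0.8687
TT	-0.1471	-0.2376	0.1246	-0.3513	-0.9651	-0.596	1.1142	0.6262	-0.9961	0.503	-0.2436	-1.8115	-1.1759	-2.0076	-0.4581	0.3998	-1.0486	1.5805	1.3745	1.6546	-0.2515	0.8116	1.8549	-0.2649	0.753	-0.8561	0.4298	0.1245	1.1133	0.7598	0.0678	0.3073	-0.8311	-0.2417	-0.8206	0.1748	0.0065	-1.4379
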