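oligo	PC01	PC02	PC03	PC04	PC05	PC06	PC07	PC08	PC09	PC10	PC11	PC12
AAA	-0.736	0.0546	-0.2253	1.0561	-1.1618	-1.9966	1.1477	0.9259	-1.2784	-0.6669	-0.4341	-0.0172
AAC	1.1063	0.5763	-0.2312	-0.2891	-0.9578	1.2393	0.7332	0.308	-2.2304	-0.2987	-1.2342	-0.5021
AAG	0.6582	-1.3684	0.8826	-1.1293	0.0081	-0.2044	-0.065	-0.1697	0.7022	0.0861	-1.3421	0.8598
AAT	0.5109	-0.3172	-0.2314	-0.7247	0.0496	-0.0296	-0.7316	0.2351	1.657	0.5503	-0.3578	-0.2545
ACA	-0.0615	0.7379	-0.9083	0.8328	-0.5393	0.0413	1.4096	-1.7671	0.3952	0.5438	0.9185	-1.5533
ACC	-0.4195	1.492	-0.4096	2.0816	0.0713	-0.318	0.3883	-0.2869	1.7552	0.9163	-1.3613	-0.2757
ACG	-0.8487	0.9039	0.0787	-1.1531	-0.272	-0.5179	2.2292	-1.2656	-1.0908	-1.627	-0.0526	0.2515
ACT	-0.3171	-0.4876	0.6433	-1.8024	-1.8079	1.1152	-0.7563	1.6382	-1.3209	1.7996	-1.4432	0.3005
AGA	-0.375	0.5109	0.105	-1.6419	1.4933	-0.3256	0.1326	0.3844	-0.0071	-1.0214	0.4012	0.0045
AGC	-0.2576	0.1558	0.1154	-0.8128	-0.6297	-0.1014	0.2168	-0.477	-0.5585	1.8335	-0.1038	0.7101
AGG	1.0002	-1.1707	-1.4737	-0.1764	0.0621	0.3283	1.2985	-1.1124	0.6008	0.3437	-1.1646	-1.1495
AGT	0.6128	1.5	2.0276	-1.7267	-0.6749	-0.8209	-0.8442	0.1131	-1.1652	0.3103	0.0257	0.3789
ATA	0.1168	1.538	-0.8821	-0.0485	0.6404	-0.995	0.3038	1.4923	-0.0062	-1.6965	-2.0734	0.1323
ATC	0.6365	0.6474	0.7159	0.492	0.6706	-0.3439	-0.6713	0.1042	1.2924	-0.6979	-0.5533	-0.1642
ATG	0.6528	0.6155	-0.3	0.1579	0.1656	0.5132	-0.881	0.3682	-0.1682	-2.6191	-0.2883	-0.6583
ATT	0.9322	-1.1887	-0.1708	0.8696	2.1355	1.1532	-1.6462	1.0349	-0.3708	-0.1037	1.4566	0.4485
CAA	-3.4757	-1.3685	0.8125	-0.5182	0.4833	-0.3992	-0.9195	-0.7194	-2.6425	-1.7341	0.8381	0.1789
CAC	1.6851	-1.0297	-1.0238	-0.2444	0.0901	1.0125	1.308	1.0957	1.9686	0.9261	1.4725	-1.0799
CAG	-0.9028	-0.9636	1.6812	1.096	-2.0777	-0.6348	-0.3771	1.3793	-2.1035	1.192	1.2911	-0.0828
CAT	0.1957	-0.054	-0.7913	0.3716	-0.0926	0.4616	0.4059	-0.1203	-2.8918	1.043	0.3986	1.6327
CCA	-0.8574	-0.8832	-0.2373	-0.6855	-0.3097	1.9014	0.5703	-0.4768	-0.7095	-0.2003	-0.1718	1.004
CCC	1.2953	-2.1898	1.9023	-0.0401	-0.4083	1.331	-0.195	-1.3811	-0.7697	-0.0688	0.3288	1.3395
CCG	-1.0218	0.7299	-1.4925	0.6796	-0.255	0.1807	-1.687	-0.8127	-2.67	0.6396	0.4464	0.2009
CCT	0.0791	-1.6067	-0.2681	-0.7402	0.0238	-2.2043	0.8631	0.7425	1.0276	-0.5638	0.1743	-0.3476
CGA	-0.2433	-1.1068	-0.7851	1.3055	-1.1042	2.709	1.9204	0.1985	1.0588	0.6444	0.2235	-0.3216
CGC	0.2546	-0.4803	1.3379	-1.6462	0.6235	-0.6842	-0.2387	1.2363	0.9674	0.8422	-0.0822	-0.121
CGG	-0.8079	-2.5432	-1.1307	-0.1143	-1.4313	0.3369	0.7253	0.775	1.6799	-0.2215	0.7238	-0.5167
CGT	-0.3322	-0.5783	-0.2371	-2.0366	0.3173	-0.0768	0.6787	0.8987	-1.9759	0.0984	-0.667	-0.3169
CTA	-0.6173	0.3492	-0.8652	0.7387	-0.3661	1.4837	0.4784	0.2646	-0.3185	-1.555	-0.7954	-1.5411
CTC	-1.6235	-0.4096	0.0101	0.456	-0.752	-0.4356	-0.5641	-0.929	-0.3594	1.0641	-0.5264	1.7106
CTG	1.0285	-0.2061	-0.422	-0.926	-0.3865	-1.6373	-0.8526	-0.5337	0.5234	-0.7696	-0.8904	-1.1913
CTT	-1.476	-1.2701	-2.0814	0.9473	0.8971	0.6256	-0.7097	-2.2215	-0.9608	-0.0174	1.6171	0.8023
GAA	0.207	-0.3425	1.0955	1.328	1.941	-0.6071	-1.3614	0.2367	-0.7503	-0.3074	1.301	-0.9377
GAC	0.4041	-0.1753	-1.0555	-0.2804	1.76	-0.7663	-0.4008	-0.6672	1.3501	-0.9656	0.5372	-0.992
GAG	0.8511	0.4769	-0.8122	-1.6914	-1.2695	0.1491	1.3594	0.067	0.9252	-0.2549	0.6072	0.4459
GAT	-1.4009	-0.648	-1.1325	0.8336	0.7357	-1.274	-1.0805	0.8344	1.6228	-0.2555	0.3303	0.9251
GCA	-0.2539	1.8564	-0.9895	-0.0988	-1.3794	1.1627	-0.0445	-0.277	-0.9406	-1.4091	-0.2518	0.3067
GCC	0.1907	1.546	-0.8016	-2.6481	-0.227	-0.0049	1.7198	0.9233	-0.5666	-0.7093	0.3309	-0.7633
GCG	-0.3583	0.0562	0.8711	-2.1948	-0.0316	1.3752	0.3025	-0.805	0.0263	-0.5494	-1.9111	0.9257
GCT	-0.4105	0.0919	-1.4647	-0.1936	-0.7903	-0.192	0.2655	-0.0736	1.1576	0.6674	0.9945	-0.0208
GGA	1.2415	1.6465	0.6071	-0.3546	1.1373	-0.8916	-0.5769	-0.7285	0.6922	-0.5524	0.5597	0.1142
GGC	0.1542	0.1122	-0.6867	-0.1948	-0.0931	-0.3946	0.654	0.7186	0.1345	0.2579	0.0399	-1.5039
GGG	0.0101	1.8005	0.6958	0.2653	0.7842	-1.049	0.0654	0.6886	-1.2715	0.3145	0.8033	0.3691
GGT	0.982	-0.8263	1.6226	-1.7985	1.1891	0.2966	0.8173	1.0306	0.6553	1.3878	1.0523	0.658
GTA	-0.5133	1.5438	0.4055	0.3205	0.1803	0.4559	0.6236	-2.0047	0.2863	0.3279	-0.415	0.6046
GTC	0.3757	0.542	-0.745	-1.0244	-0.2459	-1.3272	0.0805	-0.5827	0.5133	-1.0579	0.6813	-0.2784
GTG	-0.7026	-0.617	0.5608	-0.7485	-0.1733	1.7704	-1.9277	-1.3317	-1.4129	0.3375	-0.7772	-1.4074
GTT	1.1603	0.0252	-0.6752	2.7357	-0.7705	-0.4195	-1.2365	-1.5558	1.032	2.4642	-0.6115	0.6878
TAA	0.1873	1.5514	1.2196	1.7243	-0.3213	-0.3597	-1.1228	-0.0465	-0.3865	-0.2137	-0.1825	-0.2308
TAC	1.4493	0.3323	0.6195	-0.4929	0.1159	-0.1247	-0.4535	-0.5361	-1.1841	-0.5656	0.1822	1.0806
TAG	1.6673	-0.5661	0.8651	0.3088	-0.1306	0.1008	-0.3845	0.2871	-0.8747	-1.1009	1.9354	2.2721
TAT	1.2763	1.6369	0.4298	0.7322	-0.5256	-0.3654	-0.957	-0.7409	-0.6824	1.3234	0.4549	-0.977
TCA	-0.916	-0.0471	-0.806	-0.5745	2.0317	0.1794	0.3686	-1.2668	1.1968	0.2492	0.3712	0.9787
TCC	0.7498	0.8188	-0.3015	1.3632	0.3268	1.721	-0.0891	0.8268	-1.2497	-0.2434	-0.1082	-0.8008
TCG	-0.3551	-0.9978	0.7876	-0.0317	-1.7704	1.3086	0.1241	2.1695	0.7593	-0.9346	-0.482	-0.0919
TCT	-2.2011	1.3579	-0.2043	-0.8823	-6e-04	-0.13	1.1956	-1.5304	-0.0177	-1.1643	-0.6423	-0.9312
TGA	1.7316	1.3173	0.8066	1.1021	1.0399	1.0699	-1.2325	-0.347	-0.4646	-1.2009	0.7722	-0.356
TGC	-1.2742	-0.3266	0.4634	0.6984	0.1756	0.7049	0.8781	-0.0993	0.5872	-0.427	0.6729	-0.7955
TGG	-0.0588	0.0959	-0.6897	-1.3897	0.1396	0.4884	0.4727	-0.5402	0.388	-0.2994	-0.3674	-1.2948
TGT	-0.0306	-0.304	-1.2838	-0.6878	0.6803	1.4378	0.401	0.7206	-0.0804	0.8635	0.3533	0.0053
TTA	0.401	-0.3746	-0.7358	1.0728	-1.2594	1.3098	1.2805	0.8542	1.0706	-1.8434	-0.4358	-1.2919
TTC	-0.8526	-0.4692	-0.8834	-0.0291	-1.141	0.303	-0.0884	-1.05	0.8836	1.1937	-2.5549	1.6118
TTG	0.717	-0.522	-1.2931	1.4257	0.0414	0.315	-0.5448	0.6197	-0.9639	1.5573	-0.7809	0.4016
TTT	0.0123	-0.3554	-1.1864	-1.3857	-0.5966	1.1692	-0.211	-0.1561	0.3965	0.9636	-0.2801	0.8673
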