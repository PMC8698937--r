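marker_id	Gran	CD4T	CD8T	Bcell	NK	Mono
mk0001	0.895284	0.137414	0.057459	0.099875	0.142247	0.131418
mk0002	0.085753	0.885748	0.10938	0.12248	0.078855	0.127551
mk0003	0.110241	0.075985	0.889535	0.101058	0.101508	0.099934
mk0004	0.118432	0.162101	0.170886	0.876004	0.101333	0.103733
mk0005	0.111457	0.083382	0.06848	0.096114	0.82651	0.082166
mk0006	0.097171	0.102885	0.072933	0.098448	0.07608	0.842263
mk0007	0.899172	0.089163	0.082491	0.113799	0.099934	0.07544
mk0008	0.097473	0.84526	0.074921	0.130183	0.119143	0.076753
mk0009	0.169145	0.105197	0.823592	0.071019	0.147522	0.071527
mk0010	0.098319	0.103264	0.095105	0.848715	0.058969	0.124951
mk0011	0.141151	0.099325	0.071918	0.0981	0.821108	0.134385
mk0012	0.180756	0.102956	0.169929	0.081293	0.0919	0.833511
mk0013	0.788839	0.087635	0.102948	0.075332	0.0632	0.073378
mk0014	0.09272	0.829676	0.097752	0.084212	0.081482	0.097651
mk0015	0.096457	0.063236	0.867988	0.116997	0.080881	0.178777
mk0016	0.118528	0.09014	0.101015	0.83337	0.082112	0.170112
mk0017	0.092583	0.086985	0.09649	0.080714	0.746106	0.062201
mk0018	0.04769	0.199942	0.14752	0.1045	0.105912	0.835831
mk0019	0.731542	0.068762	0.094291	0.071211	0.084185	0.149664
mk0020	0.141706	0.855175	0.070286	0.131992	0.149176	0.098972
mk0021	0.09202	0.066279	0.864162	0.087656	0.123636	0.152129
mk0022	0.061133	0.06671	0.090901	0.857091	0.067027	0.091347
mk0023	0.095453	0.103418	0.086767	0.101386	0.853725	0.117561
mk0024	0.137902	0.076124	0.074629	0.099994	0.085071	0.858377
mk0025	0.909138	0.099951	0.112175	0.160514	0.126669	0.226443
mk0026	0.088963	0.832872	0.095399	0.079818	0.101442	0.12774
mk0027	0.093265	0.084608	0.868676	0.135453	0.085933	0.071812
mk0028	0.061446	0.057075	0.093848	0.851204	0.112475	0.084836
mk0029	0.113127	0.071448	0.083572	0.079601	0.855744	0.11045
mk0030	0.083998	0.104952	0.139176	0.098159	0.095642	0.762113
mk0031	0.866601	0.116403	0.092898	0.122046	0.169207	0.060737
mk0032	0.120705	0.830157	0.128662	0.089083	0.086587	0.073524
mk0033	0.131622	0.100002	0.798046	0.080999	0.087987	0.09099
mk0034	0.084718	0.134661	0.0881	0.85575	0.065314	0.138769
mk0035	0.114484	0.146132	0.092959	0.130035	0.848443	0.092836
mk0036	0.06225	0.074031	0.089928	0.098034	0.126738	0.856106
mk0037	0.817465	0.096877	0.142753	0.068285	0.056325	0.098269
mk0038	0.079256	0.890421	0.099387	0.069835	0.093448	0.082504
mk0039	0.051102	0.088013	0.859104	0.081081	0.072311	0.143249
mk0040	0.10098	0.098592	0.077277	0.828704	0.14621	0.074043
mk0041	0.105701	0.097699	0.081961	0.099423	0.894916	0.093999
mk0042	0.090665	0.078455	0.130357	0.119616	0.109401	0.836204
mk0043	0.876755	0.088618	0.139472	0.088862	0.145739	0.115313
mk0044	0.082018	0.84887	0.139126	0.073687	0.078898	0.152509
mk0045	0.068644	0.089367	0.78925	0.117627	0.128753	0.114753
mk0046	0.112308	0.134329	0.170479	0.860234	0.085276	0.143993
mk0047	0.080126	0.087742	0.130998	0.13587	0.861868	0.122572
mk0048	0.146291	0.088897	0.099281	0.062857	0.092202	0.824513
mk0049	0.832739	0.120451	0.120666	0.102382	0.092727	0.102223
mk0050	0.119147	0.804976	0.076658	0.142924	0.115742	0.143761
mk0051	0.109034	0.098906	0.803095	0.121322	0.069891	0.065034
mk0052	0.080737	0.065211	0.101332	0.815302	0.093426	0.109117
mk0053	0.151292	0.136217	0.071973	0.121589	0.856424	0.095846
mk0054	0.118746	0.09285	0.105249	0.078797	0.089622	0.88058
mk0055	0.853401	0.088058	0.140891	0.088407	0.102862	0.122156
mk0056	0.107719	0.796267	0.075342	0.136937	0.091714	0.108427
mk0057	0.119894	0.099791	0.819516	0.092434	0.152941	0.148125
mk0058	0.102452	0.080372	0.101264	0.879018	0.121003	0.065689
mk0059	0.043308	0.086489	0.075683	0.092407	0.932413	0.127415
mk0060	0.107959	0.140527	0.090117	0.064759	0.080487	0.779154
mk0061	0.835405	0.09536	0.126154	0.079302	0.124236	0.117025
mk0062	0.105114	0.804249	0.12939	0.074208	0.172528	0.102447
mk0063	0.116842	0.104494	0.864098	0.087663	0.108425	0.129313
mk0064	0.144636	0.090623	0.059935	0.836677	0.07432	0.102148
mk0065	0.082005	0.117096	0.098552	0.095935	0.807322	0.064898
mk0066	0.141066	0.145854	0.132643	0.093621	0.099048	0.756255
mk0067	0.862398	0.076207	0.124198	0.16389	0.141306	0.115584
mk0068	0.131739	0.866573	0.094965	0.068305	0.122163	0.098036
mk0069	0.127749	0.102316	0.715983	0.089344	0.055267	0.085604
mk0070	0.121216	0.126911	0.101658	0.862869	0.082615	0.091909
mk0071	0.075149	0.093965	0.116593	0.153333	0.849653	0.083276
mk0072	0.097591	0.124964	0.101244	0.102416	0.066941	0.843882
mk0073	0.872323	0.06176	0.104331	0.138778	0.120377	0.077514
mk0074	0.077039	0.903909	0.112271	0.063531	0.05042	0.057751
mk0075	0.086268	0.125891	0.834192	0.146375	0.103936	0.094225
mk0076	0.116817	0.096002	0.141337	0.82163	0.089922	0.131971
mk0077	0.122736	0.067112	0.113437	0.09278	0.830229	0.16328
mk0078	0.113237	0.11875	0.071093	0.073778	0.092598	0.8501
mk0079	0.812885	0.113824	0.143964	0.103673	0.108826	0.097843
mk0080	0.073976	0.849757	0.137538	0.159544	0.111221	0.129169
mk0081	0.14888	0.104164	0.878875	0.186855	0.094071	0.101456
mk0082	0.107183	0.085297	0.063209	0.804011	0.058706	0.088855
mk0083	0.102413	0.110408	0.085644	0.113907	0.786311	0.061896
mk0084	0.096783	0.108242	0.118515	0.144221	0.066725	0.795026
mk0085	0.798396	0.092709	0.101187	0.09484	0.122532	0.111518
mk0086	0.11778	0.791457	0.109797	0.094262	0.093612	0.066912
mk0087	0.094288	0.120575	0.92219	0.092067	0.107521	0.132081
mk0088	0.095173	0.11599	0.079971	0.871462	0.065076	0.069064
mk0089	0.128172	0.079576	0.055662	0.144551	0.828342	0.094894
mk0090	0.124478	0.064429	0.107636	0.120158	0.116244	0.849911
mk0091	0.895878	0.105672	0.082906	0.108983	0.095287	0.099654
mk0092	0.087858	0.836317	0.112704	0.09214	0.096934	0.104178
mk0093	0.118981	0.10703	0.816211	0.114283	0.098071	0.11736
mk0094	0.144317	0.070082	0.177466	0.827747	0.137768	0.096644
mk0095	0.07375	0.076918	0.096709	0.092709	0.824933	0.093487
mk0096	0.07904	0.133369	0.08783	0.133742	0.119794	0.85603
mk0097	0.801402	0.111442	0.0956	0.112583	0.127012	0.088886
mk0098	0.06692	0.871081	0.125818	0.106698	0.072157	0.149822
mk0099	0.10218	0.16075	0.853685	0.093307	0.103322	0.054769
mk0100	0.11907	0.103532	0.06387	0.88225	0.099697	0.131344
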