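sample	taxon001	taxon002	taxon003	taxon004	taxon005	taxon006	taxon007	taxon008	taxon009	taxon010	taxon011	taxon012	taxon013	taxon014	taxon015	taxon016	taxon017	taxon018	taxon019	taxon020
sample001	0	54097	4278	0	12393	0	0	0	2716	0	0	142	0	0	0	0	0	0	0	0
sample002	0	29119	0	0	0	0	0	0	367	0	0	0	9156	0	0	0	0	497	0	3007
sample003	0	8164	0	0	0	19708	0	0	0	0	0	571	29793	0	0	0	0	0	0	0
sample004	0	3640	5569	0	0	2895	0	7718	0	0	0	0	1626	0	0	0	0	0	30869	0
sample005	0	0	0	0	0	5741	1635	0	592	0	274	0	21823	0	0	0	1811	2078	3902	0
sample006	0	0	0	36615	0	31313	0	0	377	0	8360	0	0	0	0	0	0	0	0	0
sample007	967	0	514	0	0	54447	0	0	390	0	0	61	0	1630	0	0	0	0	0	0
sample008	0	21429	23040	0	0	0	0	0	707	0	0	0	0	0	0	0	0	1057	0	2765
sample009	0	0	0	0	0	32119	311	14560	818	0	969	80	0	0	0	0	0	0	0	2900
sample010	0	0	0	0	7329	31716	0	0	308	0	0	0	4501	0	0	0	9561	0	0	4863
sample011	0	0	5293	0	0	43622	0	0	0	0	0	0	0	0	0	0	0	0	0	0
sample012	0	0	0	17418	0	0	0	1515	723	0	0	0	0	0	0	0	0	0	0	0
sample013	0	0	7755	0	0	18635	3459	0	0	0	0	111	7620	14398	0	0	0	0	0	0
sample014	0	0	1149	0	0	40343	0	0	1255	0	0	0	0	0	0	0	0	0	0	0
sample015	0	5807	3568	0	0	0	4051	0	1646	0	0	0	1754	31690	0	0	2229	0	0	0
sample016	0	11634	2333	2459	0	0	827	30250	330	0	2663	0	3810	0	0	0	2096	0	0	599
sample017	0	2737	594	1135	6443	57590	0	0	580	0	0	0	0	971	0	0	0	0	2632	345
sample018	0	0	455	0	26284	7592	0	0	303	0	0	0	107	0	0	0	396	1087	2169	0
sample019	0	6959	963	0	0	61783	0	0	143	0	521	0	0	0	0	0	421	19	0	0
sample020	0	0	6142	8149	0	32269	0	0	114	0	418	158	0	0	0	0	0	438	0	5157
sample021	0	0	0	0	0	23739	3707	0	1188	0	0	0	36273	0	0	0	0	0	0	366
sample022	0	0	0	0	0	0	0	29407	705	0	0	312	28527	0	0	0	0	3675	0	0
sample023	0	3528	343	7356	5798	39539	0	0	108	0	0	0	2760	0	0	0	0	0	0	0
sample024	0	0	0	0	0	0	11835	9364	0	0	10662	0	0	0	0	0	0	0	0	2943
sample025	0	0	0	9656	0	36156	0	0	229	0	0	122	0	0	0	0	0	0	0	339
sample026	0	0	3948	14232	0	31186	0	0	84	0	757	0	7675	0	0	0	0	0	0	0
sample027	848	0	1514	0	0	0	0	31998	1707	0	0	0	0	0	0	0	0	0	0	0
sample028	85	5863	0	3331	0	30975	0	0	50	0	0	61	0	0	0	0	314	0	0	0
sample029	0	0	2805	0	0	49346	0	0	0	0	1148	0	0	3561	0	0	0	381	0	0
sample030	0	0	3348	0	0	50859	2848	0	0	0	0	0	1621	0	0	0	1029	270	0	0
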