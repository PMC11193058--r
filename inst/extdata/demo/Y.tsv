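sample	resp001	resp002	resp003	resp004	resp005
sample001	5.184094	-2.2991860000000002	6.3092969999999999	9.0020579999999999	-7.8201669999999996
sample002	28.307053	9.6010810000000006	-5.4042779999999997	11.108798999999999	-18.539545
sample003	-10.396768	7.884061	-17.62491	-4.1892860000000001	-15.236447
sample004	1.347229	-11.138165000000001	-8.1232830000000007	1.3538790000000001	7.3689200000000001
sample005	-0.582596	-0.56067999999999996	9.1498849999999994	-5.135389	0.65079900000000002
sample006	-37.159500000000001	2.795471	9.5219389999999997	-0.094975000000000004	9.4193160000000002
sample007	-21.925443999999999	-0.82154400000000005	-2.957792	-10.246658999999999	7.2560180000000001
sample008	2.0168529999999998	-0.76207800000000003	0.44694499999999998	-1.1796420000000001	7.8832570000000004
sample009	-35.669550000000001	-2.3872849999999999	-17.943247	3.7767849999999998	-3.7425579999999998
sample010	-8.7667400000000004	-2.9580679999999999	6.8083859999999996	-1.9376739999999999	8.9192669999999996
sample011	-24.606631	-2.6892510000000001	2.04976	-0.066942000000000002	20.961136
sample012	3.0990839999999999	-3.508114	-6.7485249999999999	17.951575999999999	-6.5013779999999999
sample013	-8.2488489999999999	-2.8991989999999999	-7.990748	-8.9069719999999997	29.552873999999999
sample014	-33.264454999999998	4.9309519999999996	-0.31166199999999999	2.5288819999999999	2.912944
sample015	20.425256000000001	15.107645	4.2977220000000003	-5.6015649999999999	-1.107715
sample016	24.945502000000001	-5.5539899999999998	-8.5612130000000004	10.726834999999999	-10.925347
sample017	-17.714372999999998	-3.0775070000000002	6.0532950000000003	-1.4983919999999999	-7.4446300000000001
sample018	-18.645707999999999	-4.7689180000000002	-4.2664689999999998	-1.071922	4.404115
sample019	-9.1323220000000003	11.432828000000001	-12.263742000000001	-1.601855	2.4461889999999999
sample020	-18.546233999999998	-8.1040489999999998	19.145042	7.2976150000000004	17.589741
sample021	3.0412499999999998	-19.623619000000001	0.96825000000000006	-0.72019599999999995	12.644405000000001
sample022	32.745469999999997	0.180479	-13.150594999999999	-2.5349810000000002	3.392944
sample023	-11.792130999999999	-16.806507	-10.02487	-10.07856	-10.15314
sample024	-0.017493000000000002	-11.021255999999999	-20.957913000000001	-3.981166	-0.17160400000000001
sample025	-28.354811999999999	8.7569339999999993	16.985628999999999	3.316122	-7.2762900000000004
sample026	-18.502414000000002	5.920973	17.256340000000002	-3.4821650000000002	17.451556
sample027	-2.0742479999999999	2.2736239999999999	-20.575099999999999	-2.7910900000000001	27.266186000000001
sample028	-18.464196000000001	-16.843758999999999	6.4699169999999997	10.703934	-11.885159
sample029	-20.247769000000002	-5.7168890000000001	2.5218189999999998	-1.574751	10.421379999999999
sample030	-5.3541160000000003	-13.435306000000001	1.15849	9.3131719999999998	25.782178999999999
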