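sample	(Intercept)	cov1
sample001	1	-0.89891600000000005
sample002	1	0.21213099999999999
sample003	1	-0.72858999999999996
sample004	1	1.23552
sample005	1	1.1688400000000001
sample006	1	-0.62248499999999996
sample007	1	0.42922199999999999
sample008	1	0.72084199999999998
sample009	1	1.699373
sample010	1	0.24678900000000001
sample011	1	0.74069499999999999
sample012	1	2.2007379999999999
sample013	1	-1.924566
sample014	1	-0.37297000000000002
sample015	1	-0.21001400000000001
sample016	1	-0.91992499999999999
sample017	1	0.062404000000000001
sample018	1	0.56013800000000002
sample019	1	-0.39873599999999998
sample020	1	0.41917599999999999
sample021	1	-0.40945300000000001
sample022	1	-0.78193599999999996
sample023	1	-0.011331000000000001
sample024	1	1.621232
sample025	1	-0.34145500000000001
sample026	1	-0.86221000000000003
sample027	1	-0.39608399999999999
sample028	1	0.44420700000000002
sample029	1	-1.387337
sample030	1	0.73609199999999997
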