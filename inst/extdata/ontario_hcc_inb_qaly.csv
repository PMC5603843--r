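lambda,strategy,inb,se,p_one_sided,probability
0,RFA,-13698,5332,0.005,0.0051
1000,RFA,-12817,5319,0.008,0.0080
10000,RFA,-4892,5300,0.178,0.1781
20000,RFA,3915,5487,0.238,0.7622
30000,RFA,12721,5872,0.015,0.9849
40000,RFA,21527,6420,0.001,0.9996
50000,RFA,30333,7093,0.001,1.0000
60000,RFA,39139,7859,0.001,1.0000
70000,RFA,47945,8693,0.001,1.0000
80000,RFA,56751,9578,0.001,1.0000
90000,RFA,65557,10501,0.001,1.0000
100000,RFA,74363,11452,0.001,1.0000
0,SR,-81536,4592,0.001,0.0001
1000,SR,-80511,4582,0.001,0.0001
10000,SR,-71287,4580,0.001,0.0001
20000,SR,-61037,4755,0.001,0.0001
30000,SR,-50787,5099,0.001,0.0001
40000,SR,-40537,5580,0.001,0.0001
50000,SR,-30288,6167,0.001,0.0001
60000,SR,-20038,6832,0.002,0.0017
70000,SR,-9788,7555,0.098,0.0976
80000,SR,462,8320,0.478,0.5221
90000,SR,10711,9117,0.120,0.8800
100000,SR,20961,9938,0.017,0.9826
0,LT,-160428,5568,0.001,0.0001
1000,LT,-158337,5554,0.001,0.0001
10000,LT,-139516,5534,0.001,0.0001
20000,LT,-118605,5731,0.001,0.0001
30000,LT,-97693,6138,0.001,0.0001
40000,LT,-76781,6717,0.001,0.0001
50000,LT,-55870,7427,0.001,0.0001
60000,LT,-34958,8235,0.001,0.0001
70000,LT,-14047,9114,0.062,0.0617
80000,LT,6865,10047,0.247,0.7528
90000,LT,27777,11019,0.006,0.9942
100000,LT,48688,12020,0.001,1.0000
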