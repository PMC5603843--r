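strategy,pyll,qalyl,mean_cost,delta_ly,delta_qaly,delta_cost,icer_ly,icer_qaly
none,11.2251,10.1149,38472,NA,NA,NA,NA,NA
TACE+RFA,9.6379,9.3606,48485,1.82717,0.93455,2304,1261,2465
RFA,10.2246,9.8759,55925,1.72958,0.88067,13697,7919,15553
RFA+SR,9.0966,9.1399,109927,2.63641,1.46756,71559,27143,48761
SR,10.0818,9.9144,119032,1.97368,1.02540,81514,41301,79495
TACE+SR,11.4624,10.9990,126514,1.09491,0.44091,96088,87759,217932
RFA+LT,12.0635,11.8248,155898,3.01967,1.88475,112411,37226,59642
TACE+LT,11.4675,11.4621,178354,3.04816,1.81332,132266,43392,72941
RFA+SR+LT,11.1088,11.2472,208484,4.10809,2.71620,164608,40069,60602
LT,11.9376,11.8696,211286,3.34719,2.09062,160430,47930,76738
SR+LT,10.7560,10.8734,222275,3.76051,2.41171,173575,46157,71972
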