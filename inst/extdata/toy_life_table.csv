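sex,age,expectancy
F,40,43
F,41,41.6
F,42,40.2
F,43,38.8
F,44,37.5
F,45,36.3
F,46,35.1
F,47,33.9
F,48,32.8
F,49,31.7
F,50,30.6
F,51,29.6
F,52,28.6
F,53,27.6
F,54,26.7
F,55,25.8
F,56,25
F,57,24.1
F,58,23.3
F,59,22.5
F,60,21.8
F,61,21.1
F,62,20.4
F,63,19.7
F,64,19
F,65,18.4
F,66,17.8
F,67,17.2
F,68,16.6
F,69,16
F,70,15.5
F,71,15
F,72,14.5
F,73,14
F,74,13.5
F,75,13.1
F,76,12.6
F,77,12.2
F,78,11.8
F,79,11.4
F,80,11
F,81,10.7
F,82,10.3
F,83,10
F,84,9.6
F,85,9.3
F,86,9
F,87,8.7
F,88,8.4
F,89,8.1
F,90,7.9
F,91,7.6
F,92,7.3
F,93,7.1
F,94,6.9
F,95,6.6
F,96,6.4
F,97,6.2
F,98,6
F,99,5.8
F,100,5.6
F,101,5.4
F,102,5.2
F,103,5
F,104,4.9
F,105,4.7
M,40,39.5
M,41,38.1
M,42,36.8
M,43,35.5
M,44,34.2
M,45,33
M,46,31.8
M,47,30.7
M,48,29.6
M,49,28.6
M,50,27.6
M,51,26.6
M,52,25.6
M,53,24.7
M,54,23.9
M,55,23
M,56,22.2
M,57,21.4
M,58,20.7
M,59,19.9
M,60,19.2
M,61,18.5
M,62,17.9
M,63,17.3
M,64,16.6
M,65,16.1
M,66,15.5
M,67,14.9
M,68,14.4
M,69,13.9
M,70,13.4
M,71,12.9
M,72,12.5
M,73,12
M,74,11.6
M,75,11.2
M,76,10.8
M,77,10.4
M,78,10.1
M,79,9.7
M,80,9.4
M,81,9
M,82,8.7
M,83,8.4
M,84,8.1
M,85,7.8
M,86,7.5
M,87,7.3
M,88,7
M,89,6.8
M,90,6.5
M,91,6.3
M,92,6.1
M,93,5.9
M,94,5.7
M,95,5.5
M,96,5.3
M,97,5.1
M,98,4.9
M,99,4.7
M,100,4.6
M,101,4.4
M,102,4.2
M,103,4.1
M,104,3.9
M,105,3.8
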