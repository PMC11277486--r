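temperature_c,event,add
15.0,E-L1,8.9
15.0,E-L2,13.7
15.0,E-L3f,21.3
15.0,E-L3m,58.8
15.0,E,8.9
15.0,L1,6.0
15.0,L2,7.9
17.5,E-L1,10.0
17.5,E-L2,24.6
17.5,E-L3f,42.8
17.5,E-L3m,65.6
17.5,E-P,94.0
17.5,E-A,191.2
17.5,E,10.0
17.5,L1,14.7
17.5,L2,18.9
17.5,L3f,23.3
17.5,L3m,26.2
17.5,P,89.2
20.0,E-L1,8.6
20.0,E-L2,22.2
20.0,E-L3f,37.0
20.0,E-L3m,69.0
20.0,E-P,97.8
20.0,E-A,184.1
20.0,E,8.6
20.0,L1,13.8
20.0,L2,15.0
20.0,L3f,39.3
20.0,L3m,31.4
20.0,P,80.5
22.4,E-L1,7.0
22.4,E-L2,19.7
22.4,E-L3f,36.6
22.4,E-L3m,58.8
22.4,E-P,88.7
22.4,E-A,181.5
22.4,E,7.0
22.4,L1,12.7
22.4,L2,17.2
22.4,L3f,25.1
22.4,L3m,37.1
22.4,P,88.2
25.0,E-L1,8.5
25.0,E-L2,21.9
25.0,E-L3f,36.2
25.0,E-L3m,67.5
25.0,E-P,93.9
25.0,E-A,175.3
25.0,E,8.5
25.0,L1,13.5
25.0,L2,14.5
25.0,L3f,36.4
25.0,L3m,29.9
25.0,P,77.8
27.5,E-L1,9.2
27.5,E-L2,20.6
27.5,E-L3f,34.6
27.5,E-L3m,62.1
27.5,E-P,86.7
27.5,E-A,172.8
27.5,E,9.2
27.5,L1,11.7
27.5,L2,14.2
27.5,L3f,31.2
27.5,L3m,28.1
27.5,P,83.0
30.0,E-L1,7.9
30.0,E-L2,19.5
30.0,E-L3f,33.4
30.0,E-L3m,57.1
30.0,E-P,86.8
30.0,E-A,179.9
30.0,E,7.9
30.0,L1,11.7
30.0,L2,14.0
30.0,L3f,26.3
30.0,L3m,35.9
30.0,P,90.2
32.5,E-L1,8.8
32.5,E-L2,20.5
32.5,E-L3f,34.5
32.5,E-L3m,67.3
32.5,E,8.8
32.5,L1,11.9
32.5,L2,14.1
32.5,P,91.5
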