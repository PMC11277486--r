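temperature_c,E,L1,L2,L3f,L3m,P
10.4,NA,NA,NA,NA,NA,NA
12.7,4.8,19.6,14.5,3.3,15.9,41.8
15.1,6.4,9.6,7.9,22.3,2.3,51.5
17.5,6.4,14.0,14.6,9.6,6.6,48.8
20.1,5.4,11.3,10.8,17.8,9.5,45.3
22.5,4.4,9.6,11.7,11.9,12.4,49.9
25.0,5.3,9.9,9.9,18.3,11.1,45.4
27.5,5.8,8.4,9.5,16.2,11.2,49.0
30.0,4.7,7.8,8.9,13.3,14.3,51.0
32.5,4.9,7.3,8.2,17.6,13.5,48.5
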