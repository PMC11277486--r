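event,dev_min,add,r2,n,range_min,range_max,calc_add_mean,calc_add_sd,regression_add_rounded,pct_deviation
E-L1,11.5,8.4,0.96,8,15.0,32.5,8.6,0.8,8,2.1
E-L2,12.9,20.4,0.99,8,15.0,32.5,20.3,2.9,20,-0.5
E-L3f,12.8,34.7,0.99,8,15.0,32.5,34.6,5.7,35,-0.4
E-L3m,11.9,62.9,0.97,8,15.0,32.5,63.3,4.4,63,0.6
E-P,10.5,91.4,0.98,6,15.0,32.5,91.3,4.2,91,-0.1
E-A,10.2,181.9,0.99,6,15.0,32.5,180.8,6.0,182,-0.6
E,11.5,8.4,0.96,8,15.0,32.5,8.6,0.8,8,2.1
L1,13.5,12.1,0.98,8,15.0,32.5,12.0,2.5,12,-1.0
L2,12.5,14.4,0.97,8,15.0,32.5,14.5,3.0,14,0.7
L3f,8.2,29.3,0.74,6,17.5,30.0,30.2,5.9,29,3.1
L3m,2.3,30.2,0.72,6,17.5,27.5,31.4,4.0,30,4.2
P,10.5,84.9,0.98,7,15.0,32.5,85.8,4.9,85,1.0
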