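eq,gas,scope,response,form,terms,coefficients,ses,intercept,intercept_se,r2,n
1,N2O,Intact live hummock,ln_offset,linear,net_min,-0.01,0.00,1.84,0.10,0.71,8
2,N2O,Intact live hummock,ln_offset,linear,no3,0.12,0.04,1.64,0.16,0.64,8
3,N2O,Intact live hollow,identity,linear,no3;soil_t,0.26;-1.4,0.07;0.46,37.2,11.62,0.88,8
4,N2O,Intact live hollow,identity,linear,no3,0.33,0.10,1.3,0.51,0.66,8
5,N2O,Intact live,ln_offset,linear,no3,0.07,0.02,1.72,0.09,0.46,16
6,N2O,Intact live,ln_offset,linear,net_nit,-0.38,0.14,1.94,0.08,0.33,16
7,N2O,mDeg live hollow,ln_offset,linear,co2,0.05,0.02,1.45,0.10,0.22,40
8,N2O,mDeg cut hummock,ln_offset,linear,co2;wt,0.07;0.02,0.02;0.01,1.49,0.11,0.38,34
9,N2O,mDeg cut hummock,ln_offset,linear,co2,0.04,0.01,1.56,0.11,0.25,40
10,N2O,mDeg cut hollow,ln_offset,linear,air_t,0.23,0.06,-5.46,1.79,0.32,34
11,N2O,hDeg live hollow,ln_offset,linear,co2,0.05,0.01,1.43,0.08,0.58,35
12,N2O,hDeg cut hummock,identity,linear,co2;wfps,0.16;0.2,0.04;0.04,-14.40,3.36,0.48,35
13,N2O,hDeg cut hollow,ln_offset,linear,co2,0.04,0.01,1.42,0.08,0.37,35
14,N2O,hDeg cut hummock,identity,linear,wfps,0.15,0.05,-7.69,3.44,0.24,35
15,N2O,hDeg,ln_offset,linear,co2;wfps,0.03;0.01,0.00;0.00,0.63,0.29,0.27,40
16,CH4,Intact live hummock,identity,linear,wt,14.24,3.27,614.15,100.46,0.30,47
17,CH4,mDeg live hummock,identity,linear,wt,18.48,4.59,786.12,101.30,0.30,40
18,CH4,mDeg live hollow,identity,linear,air_t;nh4,105.45;0.13,10.35;0.04,-2994.02,314.18,0.96,8
19,CH4,mDeg live hollow,identity,linear,air_t;net_min,103.23;0.48,12.32;0.18,-2823.16,364.24,0.94,8
20,CH4,mDeg live hollow,identity,linear,wfps;no3,-47.88;25.06,11.3;8.14,4511.85,1015.8,0.80,8
21,CH4,mDeg cut hummock,identity,linear,wt,23.14,7.12,767.13,158.30,0.22,40
22,CH4,mDeg live,identity,linear,co2;wt,21.34;15.19,10.54;3.35,388.58,120.72,0.22,80
23,CH4,hDeg live hummock,identity,linear,no3,137.74,12.52,478.91,52.58,0.95,8
24,CH4,hDeg live hummock,identity,linear,wt,21.42,4.53,934.33,135.22,0.35,44
25,CH4,hDeg cut hummock,identity,linear,wt,27.71,3.36,753.13,98.40,0.62,44
26,CH4,hDeg cut hollow,identity,linear,wt,7.58,2.04,379.60,63.89,0.25,44
27,CH4,hDeg live,identity,linear,co2;wt,18.18;16.02,6.94;3.06,386.51,146.69,0.25,88
28,CH4,hDeg cut,identity,linear,wt,16.44,2.32,538.68,70.53,0.37,88
29,CH4,hDeg,identity,linear,no3,144.13,22.66,325.80,93.22,0.74,16
30,CH4,hDeg,identity,linear,wt,14.95,1.91,616.09,58.22,0.26,176
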