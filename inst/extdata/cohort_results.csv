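case,dose_gy,time_min,n_iso,bed_orig,bed_min,bed_max,delta_rel_pct
01,12,20.80,13,61.95,60.67,63.33,4.29
02,12,24.07,8,61.62,60.63,62.88,3.67
03,12,39.06,17,58.44,55.24,60.39,8.82
04,12,41.00,14,57.07,54.80,59.04,7.42
05,12,59.32,19,57.04,50.54,56.77,10.93
06,12,72.05,19,51.87,50.05,55.07,9.68
07,13,22.37,9,71.37,70.22,72.47,3.15
08,13,22.44,4,71.70,71.43,71.29,-0.20
09,13,30.17,7,67.98,66.32,69.83,5.16
10,13,31.84,15,68.27,65.16,71.18,8.83
11,13,35.22,13,69.84,63.10,71.97,12.69
12,13,46.95,11,68.02,63.57,68.50,7.24
13,13,48.32,12,66.78,64.53,69.43,7.33
14,13,55.25,13,65.57,63.03,67.55,6.88
15,13,73.68,17,61.83,55.64,64.42,14.19
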