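# Per-run goodness of fit (RMS error, degrees) of the exponential and power
# models, with the number of line settings (data points) per run, reported for
# the 27-subject 2.5G gondola-centrifuge study.
subject,run,n,rms_exponential,rms_power
1,1,19,3.085,4.089
1,2,18,2.304,2.058
2,1,20,3.596,4.019
2,2,17,1.846,1.496
3,1,17,3.414,4.233
3,2,20,2.765,4.376
4,1,16,4.265,6.037
4,2,18,1.487,2.018
5,1,16,2.802,3.349
5,2,19,1.374,1.593
6,1,17,1.375,1.267
6,2,20,1.545,2.095
7,1,27,2.121,2.560
7,2,26,1.780,1.576
8,1,21,3.504,4.061
8,2,24,2.935,3.748
9,1,14,0.943,1.102
9,2,18,0.595,0.835
10,1,21,3.849,5.207
10,2,24,3.278,5.196
11,1,21,1.812,3.177
11,2,24,2.427,3.134
12,1,21,0.796,0.963
12,2,22,0.626,0.934
13,1,27,1.479,1.578
13,2,26,1.515,1.646
14,1,24,3.069,4.286
14,2,24,1.880,2.419
15,1,20,2.918,5.023
15,2,24,3.774,5.703
16,1,23,1.915,2.379
16,2,23,1.830,1.911
17,1,24,3.477,6.869
17,2,23,3.442,6.726
18,1,16,2.136,3.135
19,1,26,3.399,4.430
20,1,22,1.671,2.135
21,1,20,1.977,2.459
22,1,19,3.004,3.531
23,1,16,1.193,1.304
24,1,15,4.474,4.648
25,1,19,1.253,1.725
26,1,20,4.151,5.898
27,1,26,2.059,2.213
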