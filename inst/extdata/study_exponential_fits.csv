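# Per-run three-parameter exponential fits, SVH = A*exp(-b*t) + C,
# reported for the 27-subject 2.5G gondola-centrifuge study.
# F4/F360: function values at t = 4 s and t = 360 s (observation interval).
# Subjects 1-17 completed two runs; 18-27 one run. Units: degrees, b in 1/s.
subject,run,A,b,C,F4,F360
1,1,45.7,0.0223,7.7,49.6,7.9
1,2,30.3,0.0101,5.6,34.7,6.4
2,1,17.6,0.0104,6.6,23.5,7.0
2,2,31.7,0.0439,3.0,29.6,3.0
3,1,41.8,0.0101,-3.9,36.2,-2.8
3,2,48.8,0.0105,-4.0,42.8,-2.9
4,1,36.3,0.0052,-13.2,22.4,-7.6
4,2,18.3,0.022,-2.7,14.1,-2.7
5,1,22.7,0.012,1.2,22.9,1.6
5,2,11.4,0.0334,3.3,13.3,3.3
6,1,15.4,0.0084,4.8,19.7,5.5
6,2,17.8,0.0094,-0.4,16.8,0.2
7,1,14.5,0.0057,2.3,16.6,4.2
7,2,24.0,0.0163,3.6,26.1,3.6
8,1,38.4,0.012,8.5,45.1,9.0
8,2,33.2,0.019,6.3,37.1,6.4
9,1,9.8,0.0058,2.8,12.4,4.0
9,2,10.7,0.0082,3.0,13.3,3.5
10,1,46.0,0.0146,4.8,48.2,5.0
10,2,48.2,0.0172,2.3,47.3,2.4
11,1,31.7,0.0034,-16.5,14.7,-7.2
11,2,18.7,0.0087,-7.8,10.2,-7.0
12,1,16.4,0.0154,2.3,17.7,2.4
12,2,16.4,0.0302,2.2,16.8,2.2
13,1,26.5,0.0665,5.1,25.5,5.1
13,2,10.8,0.0856,1.3,9.0,1.3
14,1,27.2,0.0108,-1.0,25.0,-0.5
14,2,22.4,0.0086,-4.2,17.5,-3.1
15,1,50.7,0.0289,-3.1,42.0,-3.1
15,2,60.0,0.0278,-3.6,50.1,-3.6
16,1,19.3,0.0424,2.7,19.0,2.7
16,2,10.0,0.051,2.0,10.1,2.0
17,1,60.5,0.0041,-11.3,48.1,2.5
17,2,67.8,0.0022,-25.8,41.2,4.9
18,1,22.4,0.0074,-0.5,21.3,1.1
19,1,36.1,0.0142,7.1,41.2,7.3
20,1,18.4,0.0124,4.4,21.9,4.6
21,1,50.5,0.0161,-3.7,43.7,-3.5
22,1,19.8,0.0146,7.0,25.7,7.1
23,1,6.6,0.0216,2.2,8.3,2.2
24,1,19.2,0.0118,7.6,25.9,7.8
25,1,17.1,0.0057,-0.2,16.5,2.0
26,1,47.2,0.0208,-2.8,40.6,-2.7
27,1,11.7,0.0217,0.0,10.7,0.0
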