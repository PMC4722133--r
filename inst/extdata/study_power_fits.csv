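# Per-run three-parameter power fits, SVH = A*t^(-b) + C, reported for the
# 27-subject 2.5G gondola-centrifuge study.
# F4/F360: function values at t = 4 s and t = 360 s (observation interval).
# Subjects 1-17 completed two runs; 18-27 one run. Units: degrees; b is a
# dimensionless exponent; A in degrees*s^b. Large |A| and |C| values were
# printed rounded to integers (0.5-degree quantum).
subject,run,A,b,C,F4,F360,int_printed
1,1,112.2,0.2256,-24.7,57.4,5.0,0
1,2,3350.1,0.0026,-3294.5,43.5,4.7,0
2,1,4445.1,0.0010,-4412.2,26.7,6.8,0
2,2,61.4,0.4056,-4.4,30.6,1.3,0
3,1,4330.9,0.0027,-4265.4,49.3,-2.8,0
3,2,9509.6,0.0013,-9439.3,53.2,-2.2,0
4,1,6115.0,0.0012,-6076.2,28.6,-4.3,0
4,2,51.4,0.1498,-25.4,16.3,-4.1,0
5,1,4666.9,0.0013,-4631.4,27.0,-0.1,0
5,2,51.5,0.7716,2.6,20.3,3.2,0
6,1,84.0,0.0891,-44.5,29.7,5.2,0
6,2,3584.1,0.0012,-3558.0,20.1,0.8,0
7,1,9590.4,0.0004,-9565.3,19.8,2.5,0
7,2,308.3,0.0208,-270.8,28.8,2.0,0
8,1,9814.5,0.0010,-9748.7,52.2,8.2,0
8,2,451.5,0.0170,-404.4,36.6,4.1,0
9,1,4541.3,0.0006,-4521.3,16.2,4.0,0
9,2,9547.8,0.0003,-9527.1,16.7,3.8,0
10,1,9834.9,0.0012,-9763.8,54.8,1.9,0
10,2,1827.9,0.0062,-1763.3,48.9,-0.9,0
11,1,7757.7,0.0008,-7727.5,21.6,-6.2,0
11,2,9598.4,0.0005,-9578.9,12.8,-8.8,0
12,1,104.4,0.0472,-77.7,20.1,1.4,0
12,2,33.5,0.3271,-3.4,17.8,1.5,0
13,1,53.4,0.7321,4.0,23.3,4.7,0
13,2,26.7,1.0439,1.3,7.5,1.3,0
14,1,9671.1,0.0006,-9635.7,27.4,1.3,0
14,2,9667.6,0.0006,-9637.8,21.8,-4.3,0
15,1,105.2,0.2165,-36.3,41.7,-6.9,0
15,2,122.9,0.2169,-41.4,49.6,-7.1,0
16,1,32.6,0.4014,-1.1,17.6,2.0,0
16,2,18.9,0.5932,1.2,9.5,1.8,0
17,1,14325,0.0008,-14247,62.6,11.2,1
17,2,14077,0.0006,-14017,49.6,11.6,1
18,1,4792.0,0.0010,-4760.1,25.2,3.7,0
19,1,14577.3,0.0006,-14521,44.6,5.3,1
20,1,8776.1,0.0005,-8746.7,23.2,3.5,0
21,1,169.1,0.1296,-85.3,56.0,-6.5,0
22,1,6135.7,0.0008,-6102.3,26.7,4.6,0
23,1,22.4,0.4738,0.7,12.3,2.0,0
24,1,9211.9,0.0005,-9175.6,29.9,9.2,0
25,1,9224.8,0.0005,-9197.3,21.1,0.4,0
26,1,1906.9,0.0053,-1854.4,38.5,-6.1,0
27,1,3900.3,0.0006,-3887.1,10.0,-0.5,0
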