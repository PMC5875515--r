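position,plaque_1_mci,plaque_2_mci,plaque_3_mci
1,1.340,0.813,0.925
2,1.590,0.754,1.065
3,1.540,0.784,0.920
4,1.520,0.628,1.125
5,1.270,0.878,1.150
6,1.300,0.820,0.825
7,1.240,0.790,1.000
8,1.210,0.835,1.013
9,1.290,0.920,0.885
10,1.310,0.770,0.905
11,1.220,0.765,1.115
12,1.410,0.708,0.765
13,1.400,0.785,1.120
14,1.510,0.840,0.943
15,1.610,0.780,0.970
16,1.450,0.803,1.045
17,1.600,0.780,1.130
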