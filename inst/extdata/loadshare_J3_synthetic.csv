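# SYNTHETIC example data set: 25 three-component load-sharing systems
# generated with lindleyLS::simulate_loadshare(25, c(0.036, 0.041, 0.069),
# seed = 20201122) and rounded to 2 decimals. A stand-in on the scale of
# published three-component load-sharing analyses; not a real measurement.
system,gap_0,gap_1,gap_2
1,36.12,6.30,16.61
2,25.94,22.27,57.95
3,9.35,70.87,42.70
4,14.44,16.97,29.62
5,29.51,50.52,69.66
6,50.89,12.29,6.71
7,15.97,5.11,83.86
8,14.92,25.74,19.09
9,24.19,32.22,39.45
10,8.87,20.93,22.79
11,22.73,17.05,25.50
12,53.18,10.92,23.92
13,6.96,44.01,14.03
14,9.98,30.13,17.00
15,45.48,44.91,44.55
16,28.72,35.79,22.82
17,26.81,7.33,53.93
18,25.13,7.01,12.99
19,67.41,41.62,19.39
20,11.45,11.22,54.83
21,8.50,30.79,14.72
22,33.84,9.71,20.13
23,11.50,67.56,21.24
24,8.99,11.84,19.52
25,18.69,19.82,23.13
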