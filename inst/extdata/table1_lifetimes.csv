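# Gap times of ten five-component load-sharing systems, printed layout:
# one row per stage Y(0..4), one column per system.
stage,system_1,system_2,system_3,system_4,system_5,system_6,system_7,system_8,system_9,system_10
Y0,83.10,74.91,164.79,60.12,81.91,132.68,16.36,54.71,130.95,39.10
Y1,59.25,53.01,60.31,46.38,20.69,25.53,56.11,28.99,23.04,32.21
Y2,30.13,12.06,32.91,47.96,21.64,4.80,19.79,17.11,49.43,66.28
Y3,47.29,10.45,6.43,17.80,67.01,37.41,41.89,20.17,21.62,41.60
Y4,46.24,39.60,17.67,18.72,50.69,29.66,14.16,52.53,10.02,69.11
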