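sample,dilution,expert_cells_per_ml_1e6,automatic_median_1e6,pct_diff_median,automatic_mean_1e6,pct_diff_mean
1,2,1.57,0.91,41.8,1.14,27.2
2,5,1.89,1.92,1.6,2.13,13
3,1,3.17,3.2,0.9,3.29,3.87
4,1,4.19,3.65,12.9,3.95,5.94
5,1,4.81,5.48,14.1,6.53,35.9
6,1,5.11,3.43,33,3.65,28.5
7,1,6.97,5.71,18.1,5.71,18.1
8,1,1.00,7.31,26.9,7.67,23.3
9,1,11.8,13.9,18.3,13.7,16
10,1,12.4,14.6,17.7,14.3,15.1
11,1,12.5,11.9,4.8,17.3,38.5
12,2,12.9,13.7,6.1,14.1,8.93
13,1,13,11,15.7,10.9,16.4
14,10,13.4,16,18.9,16.4,22.1
15,1,14.3,14.2,1.2,14.6,1.67
16,1,16.7,18.3,9.6,19.4,16.2
17,10,17.4,16.9,2.8,17.6,1.1
18,2,2.00,1.6,20.1,15.2,24.2
19,1,20.2,16.9,16.2,16.4,18.9
20,1,30.5,36.5,19.9,36.2,18.8
21,1,31.7,37.9,19.5,39.2,23.6
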