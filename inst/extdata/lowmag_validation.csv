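sample,medium,expert_mean_1e6,automatic_mean_1e6,pct_diff_mean
1,1,13.36,13.17,1.5
2,1,8.31,8.58,3.2
3,1.33,12.08,11.70,3.1
4,2,8.42,8.49,0.8
5,2.86,2.03,2.15,6.2
6,4,3.78,4.00,5.9
7,6.67,2.28,2.57,12.7
8,2/acid 0.1 mL,6.89,5.69,17.4
9,2/alkali 0.1 mL,10.61,9.92,6.5
10,2/NaCl 0.1 mL,6.17,6.55,6.2
11,1.33/centrifugation,11.47,10.83,5.6
12,2/centrifugation,113.97,104.77,8.1
13,2.86/centrifugation,74.17,72.82,1.8
14,4/centrifugation,69.39,72.26,4.1
15,6.67/centrifugation,33.33,29.00,13.0
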