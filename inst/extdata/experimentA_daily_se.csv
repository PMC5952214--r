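n_fish,tank,day,basal_mean,basal_sd,event_se
50,1,1,4.92,0.14,5.16
50,1,2,4.98,0.15,5.23
50,1,3,4.73,0.11,5.00
50,1,4,4.79,0.04,4.77
50,1,5,5.09,0.28,4.82
50,2,1,4.62,0.07,4.62
50,2,2,4.66,0.09,5.68
50,2,3,4.60,0.04,4.89
50,2,4,4.63,0.08,4.84
50,2,5,4.68,0.10,4.81
25,1,1,4.71,0.01,4.85
25,1,2,4.47,0.10,4.53
25,1,3,4.50,0.14,4.41
25,1,4,4.30,0.05,4.75
25,1,5,4.46,0.11,5.46
25,2,1,4.76,0.04,4.98
25,2,2,4.78,0.22,4.76
25,2,3,4.67,0.11,4.73
25,2,4,4.67,0.10,4.58
25,2,5,4.69,0.36,5.41
13,1,1,4.11,0.23,4.27
13,1,2,4.05,0.11,3.88
13,1,3,4.75,0.45,4.43
13,1,4,4.20,0.34,4.05
13,1,5,4.34,0.55,4.40
13,2,1,3.97,0.17,4.47
13,2,2,3.99,0.20,4.40
13,2,3,4.21,0.27,4.16
13,2,4,3.99,0.08,4.02
13,2,5,3.97,0.08,4.06
1,1,1,0.59,0.39,2.79
1,1,2,1.84,0.63,2.63
1,1,3,0.97,0.77,2.26
1,1,4,1.34,0.34,2.15
1,1,5,0.87,0.03,1.49
1,2,1,0.52,0.23,2.79
1,2,2,0.73,0.19,1.63
1,2,3,0.38,0.13,2.07
1,2,4,1.40,0.47,1.50
1,2,5,2.01,0.49,2.31
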