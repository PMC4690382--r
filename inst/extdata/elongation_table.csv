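t,sk_18C,sk_26C,sk_average,fem_spindle_free,cj_25C,fem_cj_fit
0.0,1.000,1.000,1.000,1.000,1.000,1.000
0.1,1.024,1.031,1.030,1.034,1.081,1.080
0.2,1.070,1.071,1.072,1.067,1.149,1.148
0.3,1.121,1.113,1.116,1.102,1.206,1.207
0.4,1.168,1.155,1.159,1.137,1.253,1.253
0.5,1.208,1.196,1.198,1.172,1.290,1.291
0.6,1.237,1.233,1.232,1.204,1.319,1.319
0.7,1.258,1.266,1.262,1.233,1.342,1.341
0.8,1.271,1.293,1.285,1.258,1.363,1.363
0.9,1.279,1.314,1.302,1.280,1.391,1.390
1.0,1.282,1.325,1.309,1.300,1.438,1.439
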