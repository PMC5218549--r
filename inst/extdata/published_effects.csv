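variable,model1_total,model2_total,model3_direct,model3_indirect,model3_total,model4_direct,model4_indirect,model4_total
beauty,-0.018,-0.037,-0.002,-0.001,-0.003,-0.010,-0.002,-0.011
privacy,-0.113,-0.141,-0.086,-0.014,-0.100,-0.102,-0.017,-0.119
sawlog,0.343,0.314,0.294,0.047,0.342,0.270,0.045,0.315
past_harvest,0.235,0.240,0.186,0.030,0.216,0.188,0.031,0.219
dist_service_center,<0.001,-0.001,-0.001,<0.001,-0.001,-0.001,<0.001,-0.001
dist_mtnf,0.002,0.002,0.001,<0.001,0.001,0.001,<0.001,0.002
age55,-0.165,-0.180,-0.141,-0.023,-0.164,-0.141,-0.023,-0.164
male,<0.001,0.147,0.051,0.008,0.060,0.152,0.026,0.178
college,0.129,0.153,0.041,0.007,0.048,0.026,0.005,0.031
income_ge_50k,0.217,0.236,0.169,0.027,0.196,0.170,0.028,0.198
income_unknown,0.066,0.065,0.063,0.010,0.073,0.062,0.010,0.073
ge_500ac,0.037,0.043,0.005,0.001,0.005,0.030,0.005,0.035
sawtimber_volume,<0.001,<0.001,0.027,0.004,0.031,0.036,0.006,0.042
market_access,-0.002,-0.006,-0.017,-0.003,-0.020,-0.024,-0.004,-0.028
market_access_sq,<0.001,<0.001,0.001,<0.001,0.001,0.001,<0.001,0.002
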