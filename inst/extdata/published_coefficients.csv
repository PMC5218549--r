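variable,model1_coef,model1_p,model2_coef,model2_p,model3_coef,model3_p,model4_coef,model4_p
spatial_dependence,NA,NA,NA,NA,0.167,0.003,0.168,0.003
beauty,-0.058,0.788,-0.130,0.605,-0.009,0.474,-0.036,0.435
privacy,-0.354,0.121,-0.492,0.090,-0.287,0.074,-0.387,0.057
sawlog,1.076,<0.001,1.101,0.001,1.039,<0.001,1.028,<0.001
dist_service_center,<0.001,0.998,-0.002,0.572,-0.002,0.148,-0.004,0.089
past_harvest,0.736,<0.001,0.838,0.001,0.703,<0.001,0.713,<0.001
age55,-0.517,0.020,-0.632,0.021,-0.498,<0.005,-0.534,0.006
male,0.001,0.996,0.515,0.153,0.223,0.163,0.577,0.017
college,0.404,0.052,0.536,0.034,0.119,0.259,0.100,0.319
income_ge_50k,0.680,0.005,0.827,0.006,0.584,<0.005,0.647,<0.005
income_unknown,0.207,0.471,0.227,0.514,0.228,0.169,0.237,0.189
ge_500ac,0.117,0.756,0.150,0.737,-0.037,0.451,-0.115,0.371
sawtimber_volume,<0.001,0.785,<0.001,0.965,0.122,0.148,0.138,0.132
dist_mtnf,0.007,0.362,0.009,0.314,0.005,0.233,0.005,0.236
market_access,-0.005,0.938,-0.022,0.752,-0.077,0.044,-0.093,0.030
market_access_sq,<0.001,0.905,0.002,0.526,<0.005,0.075,<0.005,0.036
pct_correct,75.6,NA,73.6,NA,72.6,NA,72.4,NA
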