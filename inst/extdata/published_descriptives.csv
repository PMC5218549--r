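variable,mean_all,sd_all,mean_residential,sd_residential,mean_absentee,sd_absentee,diff_res_abs,unit
wth,0.29,0.46,0.27,0.44,0.35,0.48,-0.08,binary
beauty,0.68,0.47,0.69,0.47,0.67,0.48,0.02,binary
privacy,0.71,0.45,0.75,0.44,0.60,0.49,0.15,binary
sawlog,0.14,0.35,0.13,0.33,0.20,0.40,-0.07,binary
past_harvest,0.45,0.50,0.50,0.50,0.32,0.47,0.18,binary
dist_service_center,100.90,41.56,101.73,41.40,98.41,42.32,3.32,miles
age55,0.75,0.44,0.76,0.43,0.70,0.46,0.06,binary
male,0.82,0.38,0.82,0.38,0.80,0.40,0.02,binary
college,0.33,0.47,0.29,0.46,0.48,0.50,-0.17,binary
income_ge_50k,0.45,0.50,0.41,0.49,0.57,0.50,-0.16,binary
income_unknown,0.25,0.44,0.26,0.44,0.22,0.42,0.04,binary
absentee,0.25,0.43,NA,NA,NA,NA,NA,binary
ge_500ac,0.06,0.24,0.06,0.24,0.07,0.25,-0.01,binary
sawtimber_volume,5.21e8,1.65e8,5.46e8,1.62e8,4.45e8,1.52e8,1.01e8,cubic_feet
dist_mtnf,13.91,15.27,15.34,16.50,9.57,9.64,5.77,miles
market_access,8.63,4.98,8.16,5.12,10.03,4.319,1.87,miles
market_access_sq,99.13,96.56,92.56,95.43,119.06,98.03,26.50,miles_sq
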