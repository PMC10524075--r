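stratum,level,n_studies,sensitivity,sens_lower,sens_upper,i2_sens,specificity,spec_lower,spec_upper,i2_spec,detection_rate,dr_lower,dr_upper,i2_dr,ppv_pct,ppv_lower,ppv_upper,i2_ppv
overall,overall,103,0.73,0.69,0.77,99.2,0.92,0.90,0.94,100.0,2.87,2.61,3.15,99.4,4.80,4.37,5.23,99.7
population,chinese,28,0.56,0.46,0.66,99.7,0.91,0.85,0.94,100.0,1.67,1.25,2.09,99.7,3.23,2.63,3.83,99.8
population,other_asian,40,0.61,0.53,0.68,99.5,0.91,0.88,0.94,100.0,2.16,1.78,2.53,99.6,3.88,3.30,4.47,99.8
population,western,63,0.81,0.77,0.84,89.2,0.93,0.92,0.94,99.8,3.35,2.94,3.77,98.6,5.20,4.69,5.72,97.1
screening_type,organized,67,0.74,0.68,0.79,99.2,0.94,0.92,0.95,100.0,2.46,2.18,2.75,99.6,4.23,3.74,4.72,99.8
screening_type,opportunistic,36,0.71,0.66,0.75,59.6,0.89,0.85,0.92,99.4,6.88,5.55,8.20,84.4,7.94,6.37,9.51,90.7
wave,first,48,0.72,0.65,0.79,99.1,0.94,0.92,0.95,100.0,2.35,2.04,2.66,99.6,4.25,3.71,4.78,99.8
wave,subsequent,19,0.77,0.69,0.84,98.3,0.93,0.90,0.95,99.9,2.74,2.12,3.36,99.5,4.08,3.36,4.80,98.9
test_type,fit_only,92,0.76,0.72,0.79,98.7,0.93,0.92,0.95,99.9,3.01,2.74,3.28,99.1,5.26,4.81,5.71,99.3
test_type,ra_only,5,0.38,0.20,0.60,96.2,0.72,0.54,0.95,100.0,0.81,0.44,1.17,82.2,0.71,0.21,1.21,93.8
test_type,parallel_ra_fit,3,0.76,0.36,0.94,84.3,0.59,0.28,0.85,99.9,2.29,1.99,2.58,99.3,0.86,0.36,1.35,76.4
test_type,serial_ra_fit,3,0.24,0.04,0.69,90.3,0.97,0.93,0.99,100.0,0.28,0.18,0.38,81.5,1.53,0.00,3.13,98.1
n_specimens,one,66,0.76,0.72,0.80,98.3,0.92,0.90,0.94,99.9,3.73,3.34,4.12,99.0,6.08,5.45,6.72,99.5
n_specimens,two,12,0.76,0.61,0.87,98.9,0.94,0.92,0.96,99.9,2.11,1.46,2.76,97.5,3.45,2.72,4.18,92.2
fit_type,quantitative,66,0.77,0.73,0.80,95.5,0.92,0.90,0.94,99.9,3.92,3.51,4.32,98.1,5.76,5.34,6.18,94.5
fit_type,qualitative,25,0.73,0.66,0.80,99.3,0.95,0.94,0.96,100.0,1.93,1.61,2.24,99.3,3.68,3.05,4.31,99.6
cutoff_band,lt20,26,0.83,0.78,0.86,63.7,0.89,0.86,0.91,99.7,5.91,4.72,7.11,95.7,5.28,4.52,6.04,88.8
cutoff_band,eq20,32,0.76,0.70,0.82,99.4,0.94,0.93,0.95,100.0,2.30,1.92,2.67,99.5,4.44,3.74,5.13,99.7
cutoff_band,gt20,28,0.72,0.66,0.78,88.2,0.94,0.91,0.96,99.7,3.50,2.70,4.30,96.8,7.16,6.30,8.03,83.8
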