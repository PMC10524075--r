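cohort,strategy,positives,sensitivity,specificity,lr_pos,lr_neg,detection_rate,ppv_pct
first_time,parallel_ra_fit2,423595,0.78,0.78,3.54,0.28,1.99,0.89
first_time,ra_only,197844,0.22,0.90,2.08,0.87,0.55,0.53
first_time,fit1_only,174134,0.57,0.91,6.32,0.47,1.45,1.58
first_time,fit2_only,261119,0.70,0.86,5.13,0.35,1.77,1.29
first_time,parallel_ra_fit1,348360,0.68,0.82,3.74,0.39,1.73,0.94
first_time,serial_ra_fit1,23618,0.11,0.99,8.81,0.90,0.27,2.19
first_time,serial_ra_fit2,35368,0.13,0.98,7.13,0.89,0.33,1.78
multi_time,parallel_ra_fit2,298487,0.78,0.74,2.99,0.30,1.96,0.75
multi_time,ra_only,161172,0.26,0.86,1.88,0.86,0.67,0.47
multi_time,fit1_only,112018,0.49,0.90,5.05,0.56,1.24,1.26
multi_time,fit2_only,166771,0.63,0.86,4.33,0.44,1.58,1.09
multi_time,parallel_ra_fit1,253380,0.67,0.78,3.03,0.43,1.69,0.76
multi_time,serial_ra_fit1,19810,0.09,0.98,4.97,0.93,0.22,1.24
multi_time,serial_ra_fit2,29456,0.11,0.97,4.45,0.91,0.29,1.11
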