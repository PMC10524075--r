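cohort,row,tests,positives,screen_detected,missed,interval
first_time,all,1901360,423595,2250,1530,1047
first_time,ra_positive_only,NA,162476,188,226,NA
first_time,fit_positive_only,NA,225751,1653,1083,NA
first_time,both_positive,NA,35368,409,221,NA
first_time,both_negative,1477765,NA,NA,NA,1047
multi_time,all,1143748,298487,1342,902,644
multi_time,ra_positive_only,NA,131716,229,205,NA
multi_time,fit_positive_only,NA,137315,903,549,NA
multi_time,both_positive,NA,29456,210,118,NA
multi_time,both_negative,845261,NA,NA,NA,644
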