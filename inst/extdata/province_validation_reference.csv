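province,outcome,year,observed_pct,predicted_pct,printed_difference_pct
NL,perceived_need,2018,14.9,14.57,-0.33
NL,perceived_need,2019,16.24,14.04,-2.2
NL,perceived_need,2020,19.35,15.19,-4.16
NL,unmet_need,2018,2.43,2.07,-0.36
NL,unmet_need,2019,2.93,1.94,-0.99
NL,unmet_need,2020,2.43,1.96,-0.47
PE,perceived_need,2018,14.37,14.23,-0.14
PE,perceived_need,2019,20.92,16.34,-4.58
PE,perceived_need,2020,16.89,14.93,-1.96
PE,unmet_need,2018,3.63,3.96,0.33
PE,unmet_need,2019,2.74,4.15,1.41
PE,unmet_need,2020,2.6,3.85,1.25
NS,perceived_need,2018,19.81,19.15,-0.66
NS,perceived_need,2019,23.58,20.44,-3.14
NS,perceived_need,2020,20.56,21.33,0.77
NS,unmet_need,2018,3.43,3.52,0.09
NS,unmet_need,2019,5.78,3.55,-2.23
NS,unmet_need,2020,4.23,3.3,-0.93
NB,perceived_need,2018,17.66,18.44,0.78
NB,perceived_need,2019,17.22,19.97,2.75
NB,perceived_need,2020,20,20.83,0.83
NB,unmet_need,2018,3.05,2.85,-0.2
NB,unmet_need,2019,3.85,3.52,-0.33
NB,unmet_need,2020,3.71,3.42,-0.29
ON,perceived_need,2018,16.93,16.63,-0.30
ON,perceived_need,2019,17.35,16.94,-0.41
ON,perceived_need,2020,17.97,17.44,-0.53
ON,unmet_need,2018,3.96,3.98,0.02
ON,unmet_need,2019,4.08,4.09,0.01
ON,unmet_need,2020,4,4.29,0.29
QC,perceived_need,2018,17.08,17.65,-0.43
QC,perceived_need,2019,16.02,17.56,1.54
QC,perceived_need,2020,16.72,17.26,0.54
QC,unmet_need,2018,3.25,3.26,0.01
QC,unmet_need,2019,3.01,3.21,0.2
QC,unmet_need,2020,3.36,3.09,-0.27
MB,perceived_need,2018,18.8,19.52,0.72
MB,perceived_need,2019,18.86,19.56,0.7
MB,perceived_need,2020,16.87,20.13,3.26
MB,unmet_need,2018,3.59,4.18,0.59
MB,unmet_need,2019,5.11,4.12,-0.99
MB,unmet_need,2020,4.25,4.43,0.18
SK,perceived_need,2018,16.57,19.94,3.37
SK,perceived_need,2019,18.61,21.14,2.53
SK,perceived_need,2020,15.98,21.31,5.33
SK,unmet_need,2018,3.1,4.03,0.93
SK,unmet_need,2019,2.84,4.23,1.39
SK,unmet_need,2020,4.07,4.16,0.09
AB,perceived_need,2018,21.73,20.77,-0.96
AB,perceived_need,2019,20.02,20.91,0.89
AB,perceived_need,2020,18.92,21.49,2.57
AB,unmet_need,2018,4.52,4.41,-0.11
AB,unmet_need,2019,3.66,4.43,0.77
AB,unmet_need,2020,3.72,4.54,0.82
BC,perceived_need,2018,18.39,18.38,-0.01
BC,perceived_need,2019,19.14,18.86,-0.28
BC,perceived_need,2020,20.05,20.01,-0.04
BC,unmet_need,2018,4.28,4.16,-0.12
BC,unmet_need,2019,4.9,NA,NA
BC,unmet_need,2020,4.87,4.51,-0.36
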