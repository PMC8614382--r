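farm_type,group,mean_te,component,eur_per_ewe
french_extensive,inefficient,0.675,lambs_meat,101.58
french_extensive,inefficient,0.675,lambs_breeding,12.79
french_extensive,inefficient,0.675,culls,6.77
french_extensive,inefficient,0.675,subsidies,27.39
french_extensive,inefficient,0.675,wool_other,4.51
french_extensive,efficient,1.000,lambs_meat,109.25
french_extensive,efficient,1.000,lambs_breeding,30.37
french_extensive,efficient,1.000,culls,8.02
french_extensive,efficient,1.000,subsidies,26.35
french_extensive,efficient,1.000,wool_other,4.57
french_extensive,average,0.709,lambs_meat,102.64
french_extensive,average,0.709,lambs_breeding,15.22
french_extensive,average,0.709,culls,6.94
french_extensive,average,0.709,subsidies,27.25
french_extensive,average,0.709,wool_other,4.52
french_intensive,inefficient,0.802,lambs_meat,125.81
french_intensive,inefficient,0.802,lambs_breeding,9.94
french_intensive,inefficient,0.802,culls,10.78
french_intensive,inefficient,0.802,subsidies,25.25
french_intensive,inefficient,0.802,wool_other,5.77
french_intensive,efficient,1.000,lambs_meat,147.44
french_intensive,efficient,1.000,lambs_breeding,25.39
french_intensive,efficient,1.000,culls,10.06
french_intensive,efficient,1.000,subsidies,25.93
french_intensive,efficient,1.000,wool_other,5.81
french_intensive,average,0.873,lambs_meat,134.01
french_intensive,average,0.873,lambs_breeding,15.79
french_intensive,average,0.873,culls,10.50
french_intensive,average,0.873,subsidies,25.51
french_intensive,average,0.873,wool_other,5.79
spanish_semi_intensive,inefficient,0.798,lambs_meat,92.75
spanish_semi_intensive,inefficient,0.798,lambs_breeding,0.69
spanish_semi_intensive,inefficient,0.798,culls,2.19
spanish_semi_intensive,inefficient,0.798,subsidies,35.47
spanish_semi_intensive,inefficient,0.798,wool_other,3.91
spanish_semi_intensive,efficient,1.000,lambs_meat,100.28
spanish_semi_intensive,efficient,1.000,lambs_breeding,2.87
spanish_semi_intensive,efficient,1.000,culls,2.06
spanish_semi_intensive,efficient,1.000,subsidies,43.47
spanish_semi_intensive,efficient,1.000,wool_other,8.45
spanish_semi_intensive,average,0.874,lambs_meat,95.95
spanish_semi_intensive,average,0.874,lambs_breeding,1.61
spanish_semi_intensive,average,0.874,culls,2.13
spanish_semi_intensive,average,0.874,subsidies,38.86
spanish_semi_intensive,average,0.874,wool_other,5.85
uk_extensive,inefficient,0.722,lambs_meat,57.81
uk_extensive,inefficient,0.722,lambs_breeding,60.44
uk_extensive,inefficient,0.722,culls,17.61
uk_extensive,inefficient,0.722,subsidies,NA
uk_extensive,inefficient,0.722,wool_other,3.60
uk_extensive,efficient,1.000,lambs_meat,42.66
uk_extensive,efficient,1.000,lambs_breeding,63.91
uk_extensive,efficient,1.000,culls,30.06
uk_extensive,efficient,1.000,subsidies,NA
uk_extensive,efficient,1.000,wool_other,5.25
uk_extensive,average,0.773,lambs_meat,54.24
uk_extensive,average,0.773,lambs_breeding,61.26
uk_extensive,average,0.773,culls,20.55
uk_extensive,average,0.773,subsidies,NA
uk_extensive,average,0.773,wool_other,3.99
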