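farm_type,bin,n_farms,share_pct,mean_te
french_extensive,<0.60,66,27.38,0.496
french_extensive,0.60-0.69,52,21.58,0.649
french_extensive,0.70-0.79,47,19.50,0.749
french_extensive,0.80-0.89,41,17.02,0.844
french_extensive,0.90-0.99,10,4.15,0.953
french_extensive,1.00,25,10.37,1.000
french_intensive,<0.60,1,1.64,0.576
french_intensive,0.60-0.69,7,11.48,0.655
french_intensive,0.70-0.79,11,18.03,0.753
french_intensive,0.80-0.89,12,19.67,0.851
french_intensive,0.90-0.99,8,13.11,0.951
french_intensive,1.00,22,36.07,1.000
spanish_semi_intensive,<0.60,2,5.41,0.580
spanish_semi_intensive,0.60-0.69,3,8.11,0.647
spanish_semi_intensive,0.70-0.79,3,8.11,0.744
spanish_semi_intensive,0.80-0.89,10,27.03,0.848
spanish_semi_intensive,0.90-0.99,5,13.51,0.909
spanish_semi_intensive,1.00,14,37.83,1.000
uk_extensive,<0.60,18,15.1,0.528
uk_extensive,0.60-0.69,15,12.6,0.647
uk_extensive,0.70-0.79,37,31.1,0.744
uk_extensive,0.80-0.89,19,16.0,0.837
uk_extensive,0.90-0.99,8,6.7,0.927
uk_extensive,1.00,22,18.5,1.000
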