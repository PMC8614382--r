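farm_type,indicator,inefficient,efficient,average
french_extensive,n_farms,216,25,241
french_extensive,ewes,501,693,521
french_extensive,lambs_sold_per_farm,432,621,452
french_extensive,lambs_sold_per_ewe,0.86,0.90,0.87
french_extensive,ewes_per_alu,385,512,399
french_extensive,feed_kg_dm_per_ewe,390,307,378
french_extensive,labor_cost,68,54,66
french_extensive,feed_cost,45,40,45
french_extensive,purchased_feed,34,31,34
french_extensive,homegrown_feed,11,9,11
french_extensive,variable_capital_cost,25,30,26
french_extensive,fixed_capital_cost,81,66,78
french_extensive,production_cost,219,190,215
french_extensive,gross_revenue,153,178,157
french_extensive,gross_margin,83,108,86
french_extensive,profit,-66,-18,-58
french_intensive,n_farms,39,22,61
french_intensive,ewes,464,502,477
french_intensive,lambs_sold_per_farm,471,588,513
french_intensive,lambs_sold_per_ewe,1.01,1.17,1.07
french_intensive,ewes_per_alu,517,520,518
french_intensive,feed_kg_dm_per_ewe,486,513,496
french_intensive,labor_cost,52,51,51
french_intensive,feed_cost,57,63,60
french_intensive,purchased_feed,42,48,45
french_intensive,homegrown_feed,15,15,15
french_intensive,variable_capital_cost,28,26,27
french_intensive,fixed_capital_cost,79,71,76
french_intensive,production_cost,216,211,214
french_intensive,gross_revenue,178,214,192
french_intensive,gross_margin,93,125,105
french_intensive,profit,-38,3,-22
spanish_semi_intensive,n_farms,23,14,37
spanish_semi_intensive,ewes,829,1003,894
spanish_semi_intensive,lambs_sold_per_farm,1278,1651,1419
spanish_semi_intensive,lambs_sold_per_ewe,1.54,1.65,1.58
spanish_semi_intensive,ewes_per_alu,519,551,532
spanish_semi_intensive,feed_kg_dm_per_ewe,308,257,287
spanish_semi_intensive,labor_cost,31,31,31
spanish_semi_intensive,feed_cost,59,60,59
spanish_semi_intensive,purchased_feed,41,45,42
spanish_semi_intensive,homegrown_feed,18,15,17
spanish_semi_intensive,variable_capital_cost,9,7,9
spanish_semi_intensive,fixed_capital_cost,22,23,23
spanish_semi_intensive,production_cost,121,121,121
spanish_semi_intensive,gross_revenue,135,157,144
spanish_semi_intensive,gross_margin,67,90,77
spanish_semi_intensive,profit,14,36,23
uk_extensive,n_farms,97,22,119
uk_extensive,ewes,675,918,720
uk_extensive,lambs_sold_per_farm,460,428,454
uk_extensive,lambs_sold_per_ewe,0.68,0.48,0.63
uk_extensive,ewes_per_alu,853,1246,922
uk_extensive,feed_kg_dm_per_ewe,93.55,62.58,86.24
uk_extensive,labor_cost,35,24,32
uk_extensive,feed_cost,20,15,19
uk_extensive,purchased_feed,13,7,12
uk_extensive,homegrown_feed,7,8,7
uk_extensive,variable_capital_cost,47,45,46
uk_extensive,fixed_capital_cost,68,48,64
uk_extensive,production_cost,170,131,161
uk_extensive,gross_revenue,140,142,140
uk_extensive,gross_margin,73,82,75
uk_extensive,profit,-30,11,-21
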