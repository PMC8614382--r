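farm_type,size_class,n_farms,existing_output_eur,target_output_eur
french_extensive,small,80,37751,57088
french_extensive,medium,45,63741,97980
french_extensive,large,116,118818,155235
french_extensive,all,241,81624,111964
french_intensive,small,22,51439,55119
french_intensive,medium,13,83262,102512
french_intensive,large,26,125254,138373
french_intensive,all,61,91582,104035
spanish_semi_intensive,small,13,80270,87343
spanish_semi_intensive,medium,13,97990,121109
spanish_semi_intensive,large,11,219504,239840
spanish_semi_intensive,all,37,127890,144543
uk_extensive,small,44,38069,50571
uk_extensive,medium,46,84524,115986
uk_extensive,large,29,221813,269104
uk_extensive,all,119,100805,129113
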