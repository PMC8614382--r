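farm_type,category,n_selecting,n_efficient,n_practice_types
french_extensive,Feeding,16,25,6
french_extensive,Breeding,15,25,4
french_extensive,Gadgets and Applications,13,25,3
french_extensive,Product marketing,12,25,6
french_extensive,Information and training,10,25,5
french_extensive,Reproduction,12,25,3
french_extensive,Human resources organization,10,25,2
french_extensive,Health,8,25,4
french_extensive,Product processing,2,25,2
french_intensive,Feeding,17,22,6
french_intensive,Breeding,14,22,6
french_intensive,Gadgets and Applications,18,22,6
french_intensive,Product marketing,17,22,5
french_intensive,Information and training,17,22,4
french_intensive,Reproduction,13,22,3
french_intensive,Human resources organization,6,22,2
french_intensive,Health,3,22,2
french_intensive,Product processing,2,22,2
spanish_semi_intensive,Feeding,6,14,5
spanish_semi_intensive,Breeding,5,14,3
spanish_semi_intensive,Gadgets and Applications,6,14,3
spanish_semi_intensive,Product marketing,6,14,3
spanish_semi_intensive,Information and training,2,14,2
spanish_semi_intensive,Reproduction,6,14,2
spanish_semi_intensive,Human resources organization,6,14,2
spanish_semi_intensive,Health,2,14,1
spanish_semi_intensive,Product processing,0,14,0
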