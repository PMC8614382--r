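category,practice,n_farms,n_efficient_total
Gadgets and Applications,Electronic identification systems,49,61
Feeding,Understanding of matching animal requirements and supply,42,61
Product marketing,Certification of products,39,61
Breeding,Use of elite flocks,38,61
Breeding,System/criteria to choose best animals for replacement,37,61
Reproduction,Assisted reproduction techniques,34,61
Breeding,"Routine data collection (i.e., milk yield/quality)",33,61
Feeding,Increased forage quality,29,61
Reproduction,Improved rams and reproduction plans,27,61
Information and training,Access to abattoir feedback on carcass quality and health,27,61
Feeding,Innovative grazing practices,23,61
Feeding,Increased pasture quality,22,61
Human resources organization,Staff training courses/regular meetings to get feedback,19,61
Gadgets and Applications,On-farm data collection linked to animal ID for decision making,19,61
Information and training,Computer farm management programs,14,61
Breeding,DNA data collection and use in programs,12,61
Human resources organization,Monitorization of labour costs/efficiency,12,61
Product marketing,Branding of products for more local and direct markets,12,61
Feeding,Use of by-products to replace conventional feeds,9,61
Health,Scientific proven use of antibiotic alternatives in feeding,9,61
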