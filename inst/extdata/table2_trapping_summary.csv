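fig_species,trees_receptive,trees_vegetative,events_receptive,events_vegetative,barcode_trees_receptive,barcode_trees_vegetative,identified_receptive,identified_vegetative
F. bullenei,3,7,10,231,2,3,35,55
F. citrifolia,3,5,14,29,2,1,45,27
F. colubrinae,2,3,8,87,1,0,16,0
F. costaricana,1,1,3,3,0,0,0,0
F. dugandii,1,1,10,5,1,0,28,0
F. near trigonata,3,1,9,2,2,1,15,9
F. nymphaefolia,3,3,12,46,0,0,0,0
F. obtusifolia,5,5,11,25,2,3,40,76
F. paraensis,1,1,4,5,1,0,26,0
F. perforata,1,2,12,49,1,1,32,3
F. pertusa,1,1,8,4,1,0,10,0
F. popenoei,3,7,22,76,3,3,51,45
F. trigonata,1,2,3,40,2,0,18,0
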