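wasp_species,fig_species,shared,trend,registry
P. gemellus A,F. bullenei,TRUE,,both
P. gemellus C,F. bullenei,FALSE,,both
P. tonduzi,F. citrifolia,FALSE,,both
P. orozcoi,F. colubrinae,FALSE,-,both
P. insularis,F. colubrinae,TRUE,+,current
P. estherae,F. costaricana,FALSE,,both
P. longiceps,F. dugandii,FALSE,,both
P. lopesi,F. near trigonata,FALSE,,both
P. piceipes,F. nymphaefolia,FALSE,,both
P. hoffmeyeri A,F. obtusifolia,FALSE,,both
P. hoffmeyeri B,F. obtusifolia,FALSE,,both
P. herrei,F. paraensis,FALSE,-,both
P. 'ex paraensis',F. paraensis,FALSE,+,current
P. insularis,F. perforata,TRUE,,both
P. silvestrii,F. pertusa,FALSE,,both
P. gemellus A,F. popenoei,TRUE,,both
P. gemellus B,F. popenoei,FALSE,,both
P. grandii,F. trigonata,FALSE,,both
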