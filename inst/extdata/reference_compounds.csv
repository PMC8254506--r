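name,n_hex,n_dhex,n_mal,class,provisional
17-HGL,0,0,0,aglycone,FALSE
G-3-HGL,1,0,0,intermediate,FALSE
G-17-HGL,1,0,0,intermediate,FALSE
RGHGL,1,1,0,intermediate,FALSE
DTG 572,1,0,1,intermediate,TRUE
DTG 648,2,0,0,intermediate,TRUE
DTG 718,1,1,1,intermediate,TRUE
DTG 734,2,0,1,intermediate,TRUE
DTG 820,2,0,2,intermediate,TRUE
lyciumoside I,2,0,0,non-rhamnosylated,FALSE
lyciumoside II,3,0,0,non-rhamnosylated,FALSE
lyciumoside IV,2,1,0,rhamnosylated,FALSE
attenoside,3,1,0,rhamnosylated,TRUE
nicotianoside I,2,1,1,rhamnosylated,TRUE
nicotianoside II,2,1,2,rhamnosylated,TRUE
nicotianoside III,2,2,0,rhamnosylated,TRUE
nicotianoside IV,2,2,1,rhamnosylated,TRUE
nicotianoside V,2,2,2,rhamnosylated,TRUE
nicotianoside VI,3,1,1,rhamnosylated,TRUE
nicotianoside VII,3,1,2,rhamnosylated,TRUE
nicotianoside VIII,3,1,3,rhamnosylated,TRUE
nicotianoside IX,2,0,1,non-rhamnosylated,TRUE
nicotianoside X,2,0,2,non-rhamnosylated,TRUE
nicotianoside XI,3,0,1,non-rhamnosylated,TRUE
nicotianoside XII,3,0,2,non-rhamnosylated,TRUE
nicotianoside XIII,3,0,3,non-rhamnosylated,TRUE
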