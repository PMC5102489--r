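species,guild,mass_kg,gregarious,group_lambda
acouchi,mammal,1.0,FALSE,0
agouti,mammal,4.5,FALSE,0
grey_brocket,mammal,15,FALSE,0
red_brocket,mammal,30,FALSE,0
collared_peccary,mammal,25,TRUE,4
black_curassow,bird,3.2,FALSE,0
grey_trumpeter,bird,1.3,TRUE,6
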