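taxon,subfamily,max_total_length,female_age_maturation,longevity_class,fecundity_class
Zacco platypus,Oxygastrinae,15,1,1,1
Opsariichthys uncirostris,Oxygastrinae,30,2,2,2
Ischikauia steenackeri,Oxygastrinae,30,2,2,2
Gnathopogon caerulescens,Gobioninae,15,1,1,1
Sarcocheilichthys spp.,Gobioninae,18,2,2,2
Squalidus spp.,Gobioninae,10,1,1,1
Cyprinus carpio,Cyprininae,60,3,3,3
Carassius spp.,Cyprininae,35,3,3,3
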