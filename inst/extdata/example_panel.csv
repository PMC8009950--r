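substrate,category,analyte,rep1,rep2,rep3,unit,basis
isopod,amino_acid,Tau,9.45,9.25,9.65,g/100g,dry_weight
isopod,amino_acid,Met,0.54,0.52,0.56,g/100g,dry_weight
krill,amino_acid,Met,1.46,1.41,1.51,g/100g,dry_weight
isopod,vitamin,VB1,ND,ND,ND,mg/100g,dry_weight
isopod,vitamin,VA,<0.05,<0.05,<0.05,mg/100g,dry_weight
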