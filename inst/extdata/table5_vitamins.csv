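substrate,analyte,value,ci95,letter,unit
isopod,VA,<0.05,,,mg/100g
krill,VA,<0.05,,,mg/100g
fish,VA,0.19,0.12,,mg/100g
isopod,VD3,<2,,,ug/100g
krill,VD3,<2,,,ug/100g
fish,VD3,<2,,,ug/100g
isopod,VK1,64.0,7.45,,ug/100g
krill,VK1,<1,,,ug/100g
fish,VK1,<1,,,ug/100g
isopod,VE,9.32,0.35,c,mg/100g
krill,VE,2.53,0.07,b,mg/100g
fish,VE,0.82,0.02,a,mg/100g
isopod,VB1,ND,,,mg/100g
krill,VB1,0.04,0.01,,mg/100g
fish,VB1,ND,,,mg/100g
isopod,VB2,1.68,0.00,b,mg/100g
krill,VB2,0.12,0.02,a,mg/100g
fish,VB2,0.12,0.21,a,mg/100g
isopod,VB3,2.83,0.70,b,mg/100g
krill,VB3,1.41,1.02,a,mg/100g
fish,VB3,ND,,,mg/100g
isopod,VB5,2.43,1.29,,mg/100g
krill,VB5,ND,,,mg/100g
fish,VB5,ND,,,mg/100g
isopod,VB6,ND,,,mg/kg
krill,VB6,ND,,,mg/kg
fish,VB6,ND,,,mg/kg
isopod,VB12,ND,,,mg/kg
krill,VB12,0.849,0.45,,mg/kg
fish,VB12,ND,,,mg/kg
isopod,Folic acid,ND,,,mg/kg
krill,Folic acid,ND,,,mg/kg
fish,Folic acid,ND,,,mg/kg
isopod,VC,<1,,,mg/100g
krill,VC,<1,,,mg/100g
fish,VC,<1,,,mg/100g
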