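substrate,analyte,value,ci95,letter,unit
isopod,Calcium,90283,1536.34,c,mg/kg
krill,Calcium,21536.04,3688.32,b,mg/kg
fish,Calcium,18575.06,2630.42,a,mg/kg
isopod,Potassium,5403.4,148.76,c,mg/kg
krill,Potassium,2378.68,340.11,a,mg/kg
fish,Potassium,3352.11,294.32,b,mg/kg
isopod,Sodium,8117.13,315.41,b,mg/kg
krill,Sodium,10592.23,1528.86,c,mg/kg
fish,Sodium,4033.63,1039.12,a,mg/kg
isopod,Magnesium,4862.67,100.74,c,mg/kg
krill,Magnesium,4517.53,508.37,b,mg/kg
fish,Magnesium,1256.98,255.49,a,mg/kg
isopod,Copper,31.00,4.97,b,mg/kg
krill,Copper,70.76,18.93,c,mg/kg
fish,Copper,4.74,18.93,a,mg/kg
isopod,Ferrum,882.67,18.31,c,mg/kg
krill,Ferrum,84.27,25.04,b,mg/kg
fish,Ferrum,22.10,2.81,a,mg/kg
isopod,Zinc,62.95,6.86,b,mg/kg
krill,Zinc,52.04,7.08,a,mg/kg
fish,Zinc,74.40,10.48,c,mg/kg
isopod,Chromium,2,0.35,,mg/kg
krill,Chromium,None,,,mg/kg
fish,Chromium,None,,,mg/kg
isopod,Selenium,2.69,0.30,c,mg/kg
krill,Selenium,1.54,0.32,b,mg/kg
fish,Selenium,0.4,0.01,a,mg/kg
isopod,Manganese,60.67,6.26,a,mg/kg
krill,Manganese,2.6,0.50,c,mg/kg
fish,Manganese,25,4.97,b,mg/kg
isopod,Total phosphorus,0.43,0.05,c,%
krill,Total phosphorus,1.42,0.01,a,%
fish,Total phosphorus,1.15,0.19,b,%
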