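substrate,analyte,mean,ci95,letter,essential,flavor,aggregate,unit
isopod,Asp,4.16,0.07,a,FALSE,TRUE,FALSE,g/100g
krill,Asp,4.97,0.10,b,FALSE,TRUE,FALSE,g/100g
fish,Asp,6.68,0.05,c,FALSE,TRUE,FALSE,g/100g
isopod,Thr,1.86,0.05,a,TRUE,FALSE,FALSE,g/100g
krill,Thr,1.92,0.07,b,TRUE,FALSE,FALSE,g/100g
fish,Thr,2.98,0.07,c,TRUE,FALSE,FALSE,g/100g
isopod,Ser,1.38,0.12,a,FALSE,FALSE,FALSE,g/100g
krill,Ser,2.02,0.05,b,FALSE,FALSE,FALSE,g/100g
fish,Ser,3.18,0.05,c,FALSE,FALSE,FALSE,g/100g
isopod,Glu,4.66,0.05,a,FALSE,TRUE,FALSE,g/100g
krill,Glu,7.06,0.05,b,FALSE,TRUE,FALSE,g/100g
fish,Glu,9.62,0.01,c,FALSE,TRUE,FALSE,g/100g
isopod,Gly,6.96,0.05,c,FALSE,TRUE,FALSE,g/100g
krill,Gly,2.04,0.05,a,FALSE,TRUE,FALSE,g/100g
fish,Gly,4.43,0.07,b,FALSE,TRUE,FALSE,g/100g
isopod,Ala,2.11,0.07,a,FALSE,TRUE,FALSE,g/100g
krill,Ala,2.56,0.12,b,FALSE,TRUE,FALSE,g/100g
fish,Ala,4.35,0.07,c,FALSE,TRUE,FALSE,g/100g
isopod,Val,3.90,0.10,c,TRUE,FALSE,FALSE,g/100g
krill,Val,2.38,0.07,a,TRUE,FALSE,FALSE,g/100g
fish,Val,3.44,0.05,b,TRUE,FALSE,FALSE,g/100g
isopod,Met,0.54,0.02,a,TRUE,FALSE,FALSE,g/100g
krill,Met,1.46,0.05,b,TRUE,FALSE,FALSE,g/100g
fish,Met,1.72,0.10,c,TRUE,FALSE,FALSE,g/100g
isopod,Ile,1.19,0.05,a,TRUE,FALSE,FALSE,g/100g
krill,Ile,2.41,0.05,b,TRUE,FALSE,FALSE,g/100g
fish,Ile,2.91,0.10,c,TRUE,FALSE,FALSE,g/100g
isopod,Leu,4.26,0.05,b,TRUE,FALSE,FALSE,g/100g
krill,Leu,3.90,0.02,a,TRUE,FALSE,FALSE,g/100g
fish,Leu,5.50,0.07,c,TRUE,FALSE,FALSE,g/100g
isopod,Tyr,1.76,0.02,b,TRUE,FALSE,FALSE,g/100g
krill,Tyr,1.68,0.01,a,TRUE,FALSE,FALSE,g/100g
fish,Tyr,2.40,0.02,c,TRUE,FALSE,FALSE,g/100g
isopod,Phe,1.84,0.05,a,TRUE,FALSE,FALSE,g/100g
krill,Phe,2.39,0.10,b,TRUE,FALSE,FALSE,g/100g
fish,Phe,2.84,0.02,c,TRUE,FALSE,FALSE,g/100g
isopod,Lys,3.36,0.05,a,TRUE,FALSE,FALSE,g/100g
krill,Lys,3.72,0.02,b,TRUE,FALSE,FALSE,g/100g
fish,Lys,5.39,0.10,c,TRUE,FALSE,FALSE,g/100g
isopod,His,0.99,0.10,a,FALSE,FALSE,FALSE,g/100g
krill,His,2.01,0.02,c,FALSE,FALSE,FALSE,g/100g
fish,His,1.62,0.05,b,FALSE,FALSE,FALSE,g/100g
isopod,Arg,4.24,0.01,b,FALSE,FALSE,FALSE,g/100g
krill,Arg,2.94,0.05,a,FALSE,FALSE,FALSE,g/100g
fish,Arg,4.50,0.07,c,FALSE,FALSE,FALSE,g/100g
isopod,Pro,2.37,0.07,b,FALSE,FALSE,FALSE,g/100g
krill,Pro,1.68,0.10,a,FALSE,FALSE,FALSE,g/100g
fish,Pro,3.15,0.01,c,FALSE,FALSE,FALSE,g/100g
isopod,Cys,0.09,0.07,a,TRUE,FALSE,FALSE,g/100g
krill,Cys,1.34,0.05,b,TRUE,FALSE,FALSE,g/100g
fish,Cys,1.37,0.05,b,TRUE,FALSE,FALSE,g/100g
isopod,Trp,0.61,0.02,a,TRUE,FALSE,FALSE,g/100g
krill,Trp,0.88,0.10,b,TRUE,FALSE,FALSE,g/100g
fish,Trp,0.62,0.02,a,TRUE,FALSE,FALSE,g/100g
isopod,Tau,9.45,0.20,c,FALSE,TRUE,FALSE,g/100g
krill,Tau,2.93,0.10,b,FALSE,TRUE,FALSE,g/100g
fish,Tau,2.04,0.12,a,FALSE,TRUE,FALSE,g/100g
isopod,SumAA,55.61,1.91,b,FALSE,FALSE,TRUE,g/100g
krill,SumAA,50.11,0.92,a,FALSE,FALSE,TRUE,g/100g
fish,SumAA,68.55,0.75,c,FALSE,FALSE,TRUE,g/100g
isopod,SumEAA,19.57,1.44,a,FALSE,FALSE,TRUE,g/100g
krill,SumEAA,20.73,1.69,b,FALSE,FALSE,TRUE,g/100g
fish,SumEAA,27.74,1.04,c,FALSE,FALSE,TRUE,g/100g
isopod,SumNEAA,36.73,1.41,b,FALSE,FALSE,TRUE,g/100g
krill,SumNEAA,29.41,0.45,a,FALSE,FALSE,TRUE,g/100g
fish,SumNEAA,40.63,2.66,c,FALSE,FALSE,TRUE,g/100g
isopod,SumFAA,27.45,1.17,b,FALSE,FALSE,TRUE,g/100g
krill,SumFAA,19.54,2.24,a,FALSE,FALSE,TRUE,g/100g
fish,SumFAA,27.28,0.27,b,FALSE,FALSE,TRUE,g/100g
isopod,SumEAA/SumAA,35.21,1.14,a,FALSE,FALSE,TRUE,%
krill,SumEAA/SumAA,41.38,2.51,b,FALSE,FALSE,TRUE,%
fish,SumEAA/SumAA,40.47,1.24,b,FALSE,FALSE,TRUE,%
isopod,SumEAA/SumNEAA,53.29,2.78,a,FALSE,FALSE,TRUE,%
krill,SumEAA/SumNEAA,70.52,5.14,b,FALSE,FALSE,TRUE,%
fish,SumEAA/SumNEAA,68.34,2.01,b,FALSE,FALSE,TRUE,%
isopod,SumFAA/SumAA,49.37,1.19,a,FALSE,FALSE,TRUE,%
krill,SumFAA/SumAA,38.98,4.37,b,FALSE,FALSE,TRUE,%
fish,SumFAA/SumAA,39.80,0.45,b,FALSE,FALSE,TRUE,%
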