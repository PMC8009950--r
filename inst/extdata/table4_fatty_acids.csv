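substrate,analyte,value,ci95,letter,class,aggregate,unit
isopod,C14:0,1.95,0.10,a,SFA,FALSE,% of total FA
krill,C14:0,8.90,0.05,c,SFA,FALSE,% of total FA
fish,C14:0,5.90,0.10,b,SFA,FALSE,% of total FA
isopod,C16:0,27.33,0.02,a,SFA,FALSE,% of total FA
krill,C16:0,22.89,0.02,b,SFA,FALSE,% of total FA
fish,C16:0,17.32,0.05,c,SFA,FALSE,% of total FA
isopod,C17:0,None,,,SFA,FALSE,% of total FA
krill,C17:0,0.26,0.07,,SFA,FALSE,% of total FA
fish,C17:0,0.58,0.05,,SFA,FALSE,% of total FA
isopod,C18:0,4.39,0.05,c,SFA,FALSE,% of total FA
krill,C18:0,1.20,0.05,a,SFA,FALSE,% of total FA
fish,C18:0,2.78,0.02,b,SFA,FALSE,% of total FA
isopod,SumSFA,33.66,4.99,b,SFA,TRUE,% of total FA
krill,SumSFA,33.13,3.00,b,SFA,TRUE,% of total FA
fish,SumSFA,26.88,3.16,a,SFA,TRUE,% of total FA
isopod,C16:1,11.22,0.07,c,MUFA,FALSE,% of total FA
krill,C16:1,6.93,0.05,a,MUFA,FALSE,% of total FA
fish,C16:1,8.31,0.07,b,MUFA,FALSE,% of total FA
isopod,C17:1,None,,,MUFA,FALSE,% of total FA
krill,C17:1,None,,,MUFA,FALSE,% of total FA
fish,C17:1,0.32,0.05,,MUFA,FALSE,% of total FA
isopod,C18:1n9,7.48,0.02,a,MUFA,FALSE,% of total FA
krill,C18:1n9,18.0,0.05,c,MUFA,FALSE,% of total FA
fish,C18:1n9,15.29,0.02,b,MUFA,FALSE,% of total FA
isopod,C20:1n9,None,,,MUFA,FALSE,% of total FA
krill,C20:1n9,1.64,0.05,b,MUFA,FALSE,% of total FA
fish,C20:1n9,0.85,0.07,a,MUFA,FALSE,% of total FA
isopod,C22:1n9,None,,,MUFA,FALSE,% of total FA
krill,C22:1n9,None,,,MUFA,FALSE,% of total FA
fish,C22:1n9,1.19,0.05,,MUFA,FALSE,% of total FA
isopod,C24:1n9,0.57,0.05,,MUFA,FALSE,% of total FA
krill,C24:1n9,None,,,MUFA,FALSE,% of total FA
fish,C24:1n9,0.81,0.12,,MUFA,FALSE,% of total FA
isopod,SumMUFA,19.28,3.03,a,MUFA,TRUE,% of total FA
krill,SumMUFA,26.57,1.14,b,MUFA,TRUE,% of total FA
fish,SumMUFA,26.61,1.86,b,MUFA,TRUE,% of total FA
isopod,C18:2n6,10.11,0.10,c,PUFA,FALSE,% of total FA
krill,C18:2n6,3.10,0.12,b,PUFA,FALSE,% of total FA
fish,C18:2n6,1.79,0.05,a,PUFA,FALSE,% of total FA
isopod,C18:3n6,0.33,0.02,c,PUFA,FALSE,% of total FA
krill,C18:3n6,0.40,0.02,b,PUFA,FALSE,% of total FA
fish,C18:3n6,0.04,0.01,a,PUFA,FALSE,% of total FA
isopod,C18:3n3,3.41,0.05,c,PUFA,FALSE,% of total FA
krill,C18:3n3,0.94,0.05,b,PUFA,FALSE,% of total FA
fish,C18:3n3,1.05,0.02,a,PUFA,FALSE,% of total FA
isopod,C20:2n6,0.5,0.05,a,PUFA,FALSE,% of total FA
krill,C20:2n6,4.21,0.10,c,PUFA,FALSE,% of total FA
fish,C20:2n6,2.06,0.07,b,PUFA,FALSE,% of total FA
isopod,C20:3n6,0.29,0.05,a,PUFA,FALSE,% of total FA
krill,C20:3n6,0.32,0.07,a,PUFA,FALSE,% of total FA
fish,C20:3n6,12.94,0.10,b,PUFA,FALSE,% of total FA
isopod,C20:3n3,0.31,0.05,,PUFA,FALSE,% of total FA
krill,C20:3n3,None,,,PUFA,FALSE,% of total FA
fish,C20:3n3,0.31,0.02,,PUFA,FALSE,% of total FA
isopod,C20:4n6,None,,,PUFA,FALSE,% of total FA
krill,C20:4n6,0.51,0.15,,PUFA,FALSE,% of total FA
fish,C20:4n6,0.70,0.05,,PUFA,FALSE,% of total FA
isopod,C20:5n3,6.54,0.02,a,PUFA,FALSE,% of total FA
krill,C20:5n3,18.30,0.05,c,PUFA,FALSE,% of total FA
fish,C20:5n3,14.70,0.05,b,PUFA,FALSE,% of total FA
isopod,C22:5n3,0.62,0.05,b,PUFA,FALSE,% of total FA
krill,C22:5n3,0.44,0.07,a,PUFA,FALSE,% of total FA
fish,C22:5n3,1.13,0.05,c,PUFA,FALSE,% of total FA
isopod,C22:6n3,1.27,0.07,a,PUFA,FALSE,% of total FA
krill,C22:6n3,12.30,0.05,b,PUFA,FALSE,% of total FA
fish,C22:6n3,12.95,0.15,c,PUFA,FALSE,% of total FA
isopod,EPA+DPA+DHA,8.40,0.67,a,PUFA,TRUE,% of total FA
krill,EPA+DPA+DHA,31.01,3.88,c,PUFA,TRUE,% of total FA
fish,EPA+DPA+DHA,28.70,2.71,b,PUFA,TRUE,% of total FA
isopod,Sum n-3 PUFA,12.12,0.75,a,PUFA,TRUE,% of total FA
krill,Sum n-3 PUFA,31.96,3.90,b,PUFA,TRUE,% of total FA
fish,Sum n-3 PUFA,30.06,2.71,b,PUFA,TRUE,% of total FA
isopod,Sum n-6 PUFA,11.50,1.74,b,PUFA,TRUE,% of total FA
krill,Sum n-6 PUFA,8.55,0.47,a,PUFA,TRUE,% of total FA
fish,Sum n-6 PUFA,17.18,3.97,c,PUFA,TRUE,% of total FA
isopod,SumPUFA,23.61,2.50,a,PUFA,TRUE,% of total FA
krill,SumPUFA,40.50,4.37,b,PUFA,TRUE,% of total FA
fish,SumPUFA,47.27,6.68,c,PUFA,TRUE,% of total FA
isopod,n-3/n-6,1.06,0.10,a,PUFA,TRUE,ratio
krill,n-3/n-6,3.74,0.25,b,PUFA,TRUE,ratio
fish,n-3/n-6,1.76,0.25,c,PUFA,TRUE,ratio
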