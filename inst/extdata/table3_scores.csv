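index,category,substrate,value
AAS,Ile,isopod,0.30
AAS,Ile,krill,0.60
AAS,Ile,fish,0.73
AAS,Leu,isopod,0.61
AAS,Leu,krill,0.55
AAS,Leu,fish,0.78
AAS,Lys,isopod,0.62
AAS,Lys,krill,0.68
AAS,Lys,fish,0.99
AAS,Thr,isopod,0.47
AAS,Thr,krill,0.48
AAS,Thr,fish,0.75
AAS,Val,isopod,0.79
AAS,Val,krill,0.48
AAS,Val,fish,0.69
AAS,Trp,isopod,0.64
AAS,Trp,krill,0.92
AAS,Trp,fish,0.65
AAS,Met+Cys,isopod,0.18
AAS,Met+Cys,krill,0.80
AAS,Met+Cys,fish,0.88
AAS,Phe+Tyr,isopod,0.59
AAS,Phe+Tyr,krill,0.67
AAS,Phe+Tyr,fish,0.86
CS,Ile,isopod,0.22
CS,Ile,krill,0.46
CS,Ile,fish,0.55
CS,Leu,isopod,0.50
CS,Leu,krill,0.46
CS,Leu,fish,0.64
CS,Lys,isopod,0.48
CS,Lys,krill,0.53
CS,Lys,fish,0.76
CS,Thr,isopod,0.40
CS,Thr,krill,0.41
CS,Thr,fish,0.64
CS,Val,isopod,0.59
CS,Val,krill,0.36
CS,Val,fish,0.53
CS,Trp,isopod,0.36
CS,Trp,krill,0.52
CS,Trp,fish,0.37
CS,Met+Cys,isopod,0.10
CS,Met+Cys,krill,0.45
CS,Met+Cys,fish,0.50
CS,Phe+Tyr,isopod,0.40
CS,Phe+Tyr,krill,0.45
CS,Phe+Tyr,fish,0.58
EAAI,all,isopod,34.13
EAAI,all,krill,45.16
EAAI,all,fish,55.93
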