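experiment,group,slot,category,proportion,quantity
Exp-1,1,1,3,0.10,136
Exp-1,1,2,5,0.20,391
Exp-1,1,3,7,0.30,324
Exp-1,2,1,0,0.40,534
Exp-1,2,2,4,0.50,875
Exp-1,2,3,6,0.60,787
Exp-1,3,1,1,0.70,1092
Exp-1,3,2,8,0.80,1610
Exp-1,3,3,2,0.90,1021
Exp-2,1,1,4,0.05,60
Exp-2,1,2,5,0.10,132
Exp-2,1,3,2,0.15,220
Exp-2,2,1,7,0.20,170
Exp-2,2,2,6,0.30,358
Exp-2,2,3,1,0.40,762
Exp-2,3,1,3,0.50,553
Exp-2,3,2,8,0.60,1370
Exp-2,3,3,0,0.70,819
Exp-3,1,1,5,0.01,164
Exp-3,1,2,8,0.05,66
Exp-3,1,3,2,0.10,19
Exp-3,2,1,0,0.20,285
Exp-3,2,2,6,0.30,323
Exp-3,2,3,7,0.40,284
Exp-3,3,1,3,0.70,746
Exp-3,3,2,4,0.80,966
Exp-3,3,3,1,0.90,1446
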