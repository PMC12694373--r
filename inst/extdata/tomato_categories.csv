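category,name,lab_count,env_count
0,Early Blight,998,922
1,Healthy,1000,1001
2,Late Blight,1201,1325
3,Leaf Miner,900,972
4,Leaf Mold,1200,1202
5,Mosaic Virus,1100,1338
6,Septoria,1100,1229
7,Spider Mites,700,849
8,Yellow Leaf Curl Virus,1500,1552
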