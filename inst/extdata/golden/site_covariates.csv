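transect,year,veg1,veg2,veg3,veg4,water1,water2,water3,water4,litter1,litter2,litter3,litter4
1,1,0.20000000000000001,0.59999999999999998,0.20000000000000001,0,0.20000000000000001,0.59999999999999998,0.20000000000000001,0,0.20000000000000001,0,0.59999999999999998,0.20000000000000001
1,2,0,0.40000000000000002,0.40000000000000002,0.20000000000000001,0.40000000000000002,0.59999999999999998,0,0,0,0.20000000000000001,0.40000000000000002,0.40000000000000002
2,1,0.59999999999999998,0,0.40000000000000002,0,0.20000000000000001,0.20000000000000001,0.20000000000000001,0.40000000000000002,0,0.40000000000000002,0.20000000000000001,0.40000000000000002
2,2,0.59999999999999998,0,0.20000000000000001,0.20000000000000001,0.20000000000000001,0.40000000000000002,0,0.40000000000000002,0.20000000000000001,0.40000000000000002,0.40000000000000002,0
3,1,0.20000000000000001,0.59999999999999998,0,0.20000000000000001,0.40000000000000002,0.20000000000000001,0,0.40000000000000002,0.20000000000000001,0.20000000000000001,0,0.59999999999999998
3,2,0.40000000000000002,0.20000000000000001,0.40000000000000002,0,0.20000000000000001,0.20000000000000001,0.40000000000000002,0.20000000000000001,0,0.20000000000000001,0.40000000000000002,0.40000000000000002
4,1,0.20000000000000001,0.40000000000000002,0,0.40000000000000002,0.59999999999999998,0.20000000000000001,0.20000000000000001,0,0,0.20000000000000001,0.59999999999999998,0.20000000000000001
4,2,0.40000000000000002,0,0.20000000000000001,0.40000000000000002,0.40000000000000002,0,0.20000000000000001,0.40000000000000002,0.59999999999999998,0.20000000000000001,0,0.20000000000000001
5,1,0.59999999999999998,0.20000000000000001,0,0.20000000000000001,0.40000000000000002,0.20000000000000001,0,0.40000000000000002,0.20000000000000001,0.40000000000000002,0.20000000000000001,0.20000000000000001
5,2,0.20000000000000001,0,0.80000000000000004,0,0,0.20000000000000001,0.20000000000000001,0.59999999999999998,0.20000000000000001,0.20000000000000001,0.20000000000000001,0.40000000000000002
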