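transect,year,visit,count
1,1,1,18
1,1,2,20
1,1,3,21
1,2,1,29
1,2,2,29
1,2,3,27
2,1,1,5
2,1,2,9
2,1,3,4
2,2,1,11
2,2,2,11
2,2,3,7
3,1,1,12
3,1,2,12
3,1,3,14
3,2,1,14
3,2,2,15
3,2,3,11
4,1,1,12
4,1,2,14
4,1,3,18
4,2,1,16
4,2,2,13
4,2,3,12
5,1,1,11
5,1,2,8
5,1,3,13
5,2,1,11
5,2,2,16
5,2,3,17
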