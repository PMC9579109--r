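id,zone,coastal,area_km2,x_km,y_km,neighbors
1,nearshore,TRUE,50,2,5,2;3
2,nearshore,FALSE,60,8,10,1;3;4
3,nearshore,TRUE,50,2,15,2;4;1;5
4,nearshore,FALSE,60,8,20,3;5;2;6
5,nearshore,TRUE,50,2,25,4;6;3;7
6,nearshore,FALSE,60,8,30,5;7;4;8
7,nearshore,TRUE,50,2,35,6;8;5
8,offshore,FALSE,400,30,38,9;10;7;6
9,offshore,FALSE,400,30,46,8;10;11
10,offshore,FALSE,400,30,54,9;11;8
11,offshore,FALSE,400,30,62,10;9
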