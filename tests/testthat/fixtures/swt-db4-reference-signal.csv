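0.439952034584
0.969278271497
0.761132468095
0.171984499144
0.424559115475
2.223187431775
-0.132120842239
1.160036550413
0.349402947558
-0.388332094034
0.505231427553
1.397366263653
0.681203628292
1.210183092720
-1.474052534869
0.265130185984
1.111837107995
0.050732845518
-0.543827589195
0.203660988658
-1.343493298555
0.729529312743
1.172075184925
0.957200350661
1.557975212399
-0.687692698932
-1.213283009040
-0.947424758645
1.047954860845
0.645664387936
-0.862249251061
0.162412146793
0.042373597480
-0.220826817609
0.690983937283
0.671064490814
0.675783024274
-0.774989126486
1.509366584625
0.498617280407
1.841219589783
0.637089750754
-0.250429980331
0.109067970618
-0.108943130372
-1.777897584080
-0.491156652561
1.918701015707
0.042086589046
-0.656691478113
0.274090403181
1.775307432800
-0.788905629159
0.949557215652
0.535294358927
-0.220615961503
1.653760627471
1.772649659453
0.372872534246
0.261102870758
-0.871528050965
0.212542627280
2.677869149134
-0.202043898731
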