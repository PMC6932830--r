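# id group diameter density x y z outer_diameter
1 HET 1.066377165786e-06 1.500000000000e+02 8.209462941159e-05 6.470601938199e-05 5.331885828928e-07 1.066377165786e-06
2 HET 1.093030974909e-06 1.500000000000e+02 7.829327622894e-05 5.530363116413e-05 5.465154874546e-07 1.093030974909e-06
3 HET 1.143213340838e-06 1.500000000000e+02 5.297195801977e-05 7.893562316895e-05 5.716066704190e-07 1.143213340838e-06
4 HET 1.227051947499e-06 1.500000000000e+02 2.333120233379e-06 4.772300650366e-05 6.135259737493e-07 1.227051947499e-06
5 HET 1.050420482759e-06 1.500000000000e+02 7.323137386702e-05 6.927315564826e-05 5.252102413797e-07 1.050420482759e-06
6 HET 1.224597421242e-06 1.500000000000e+02 4.776196221355e-05 8.612094768323e-05 6.122987106210e-07 1.224597421242e-06
7 HET 1.236168817151e-06 1.500000000000e+02 4.380971072242e-05 2.447972770315e-05 6.180844085757e-07 1.236168817151e-06
8 HET 1.165199448122e-06 1.500000000000e+02 7.067904714495e-06 9.946616017260e-06 5.825997240609e-07 1.165199448122e-06
9 HET 1.157278510975e-06 1.500000000000e+02 3.162717071828e-05 5.186342631932e-05 5.786392554874e-07 1.157278510975e-06
10 HET 1.015446567617e-06 1.500000000000e+02 6.620050764177e-05 4.068301871885e-05 5.077232838084e-07 1.015446567617e-06
11 HET 1.051493643725e-06 1.500000000000e+02 9.128759242594e-05 2.936033727601e-05 5.257468218624e-07 1.051493643725e-06
12 HET 1.044139188132e-06 1.500000000000e+02 4.590657262597e-05 3.323946741875e-05 5.220695940661e-07 1.044139188132e-06
13 HET 1.171755711664e-06 1.500000000000e+02 6.508704670705e-05 2.580167807173e-05 5.858778558322e-07 1.171755711664e-06
14 HET 1.096025929553e-06 1.500000000000e+02 4.785452482756e-05 7.663106706459e-05 5.480129647767e-07 1.096025929553e-06
15 HET 1.192460355000e-06 1.500000000000e+02 8.424691436812e-06 8.753213300370e-05 5.962301774998e-07 1.192460355000e-06
16 HET 1.124424810521e-06 1.500000000000e+02 3.390729378443e-05 8.394403501879e-05 5.622124052607e-07 1.124424810521e-06
17 HET 1.179404627066e-06 1.500000000000e+02 3.466834891587e-05 3.337749307975e-05 5.897023135331e-07 1.179404627066e-06
18 HET 1.247976523708e-06 1.500000000000e+02 4.763512450736e-05 8.921983358450e-05 6.239882618538e-07 1.247976523708e-06
19 HET 1.095008794859e-06 1.500000000000e+02 8.643394706305e-05 3.899895434733e-05 5.475043974293e-07 1.095008794859e-06
20 HET 1.194361305330e-06 1.500000000000e+02 7.773206988350e-05 9.606179972179e-05 5.971806526650e-07 1.194361305330e-06
21 AOB 1.233676307776e-06 1.500000000000e+02 4.346594847739e-05 7.125146787148e-05 6.168381538882e-07 1.233676307776e-06
22 AOB 1.053035630321e-06 1.500000000000e+02 3.999943688978e-05 3.253521518782e-05 5.265178151603e-07 1.053035630321e-06
23 AOB 1.162918441521e-06 1.500000000000e+02 7.570871480275e-05 2.026922551449e-05 5.814592207607e-07 1.162918441521e-06
24 AOB 1.031388773990e-06 1.500000000000e+02 7.111212224700e-05 1.216919210274e-05 5.156943869952e-07 1.031388773990e-06
25 AOB 1.066805167182e-06 1.500000000000e+02 2.454885139596e-05 1.433043794241e-05 5.334025835909e-07 1.066805167182e-06
26 AOB 1.096528523136e-06 1.500000000000e+02 2.396294150967e-05 5.893437727354e-06 5.482642615680e-07 1.096528523136e-06
27 AOB 1.003347583290e-06 1.500000000000e+02 6.422882585321e-05 8.762692126911e-05 5.016737916449e-07 1.003347583290e-06
28 AOB 1.095596989268e-06 1.500000000000e+02 7.789146774448e-05 7.973088258877e-05 5.477984946338e-07 1.095596989268e-06
29 AOB 1.217422711430e-06 1.500000000000e+02 4.552744536195e-05 4.100840820465e-05 6.087113557151e-07 1.217422711430e-06
30 AOB 1.085087249172e-06 1.500000000000e+02 8.108702427708e-05 6.049332902767e-05 5.425436245860e-07 1.085087249172e-06
31 NOB 1.120520028868e-06 1.500000000000e+02 6.547239280771e-05 3.531972719356e-05 5.602600144339e-07 1.120520028868e-06
32 NOB 1.149891456356e-06 1.500000000000e+02 2.702601458877e-05 9.926840611733e-05 5.749457281781e-07 1.149891456356e-06
33 NOB 1.123385326762e-06 1.500000000000e+02 6.334932644386e-05 2.132081352174e-05 5.616926633811e-07 1.123385326762e-06
34 NOB 1.046554400353e-06 1.500000000000e+02 1.293723480776e-05 4.781180343125e-05 5.232772001764e-07 1.046554400353e-06
35 NOB 1.206843329652e-06 1.500000000000e+02 9.240744698327e-05 5.987609671429e-05 6.034216648259e-07 1.206843329652e-06
36 NOB 1.167116684548e-06 1.500000000000e+02 9.761706949212e-05 7.317925118841e-05 5.835583422740e-07 1.167116684548e-06
37 NOB 1.198559965182e-06 1.500000000000e+02 3.567269120831e-05 4.314736905508e-05 5.992799825908e-07 1.198559965182e-06
38 NOB 1.026985906472e-06 1.500000000000e+02 1.482115606777e-05 1.307757548057e-06 5.134929532360e-07 1.026985906472e-06
39 NOB 1.180927736510e-06 1.500000000000e+02 7.155660660937e-05 1.031842357479e-05 5.904638682550e-07 1.180927736510e-06
40 NOB 1.102818607411e-06 1.500000000000e+02 4.462843486108e-05 6.401010451373e-05 5.514093037054e-07 1.102818607411e-06
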