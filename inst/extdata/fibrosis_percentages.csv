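image_id,group,width_orig,height_orig,width_matlab,height_matlab,manual_px,matlab_px,python_px,gabor_px,manual_pct,matlab_pct,python_pct,gabor_pct
1,fibrosis,921,616,1155,774,215716,148047,138737,541410,38.02,16.56,24.45,60.56
2,fibrosis,921,616,1155,774,140224,119555,140706,326481,24.72,13.37,24.80,36.52
3,fibrosis,921,616,1155,774,240895,149127,144542,570221,42.46,16.68,25.48,63.79
4,fibrosis,921,616,1155,774,270748,172357,160072,739971,47.72,19.28,28.21,82.77
5,fibrosis,921,616,1155,774,386553,231284,257170,634222,68.13,25.87,45.33,70.94
6,fibrosis,921,616,1155,774,410440,217715,223937,663299,72.35,24.35,39.47,74.20
7,fibrosis,921,616,1155,774,252138,164117,157676,591254,44.44,18.36,27.79,66.14
8,fibrosis,921,616,1155,774,315264,172637,159021,353707,55.57,19.31,28.03,39.57
9,fibrosis,921,616,1155,774,342680,218218,259063,516978,60.40,24.41,45.66,57.83
10,fibrosis,921,616,1155,774,307601,203399,195596,437666,54.22,22.75,34.48,48.96
11,fibrosis,921,616,1155,774,177975,137546,141415,328988,31.37,15.39,24.93,36.80
12,fibrosis,1115,616,1398,774,63795,208554,235216,399743,9.29,19.27,34.25,36.94
13,fibrosis,1115,616,1398,774,73447,210744,238345,395091,10.69,19.48,34.70,36.51
14,fibrosis,1115,616,1398,774,167816,269490,301505,741204,24.43,24.91,43.90,68.50
15,fibrosis,1115,616,1398,774,82008,202507,274541,485990,11.94,18.72,39.97,44.91
16,fibrosis,1115,616,1398,774,115202,232695,283967,547571,16.77,21.50,41.34,50.60
17,fibrosis,1115,616,1398,774,112765,236892,266986,811449,16.42,21.89,38.87,74.99
18,fibrosis,937,616,1175,774,133159,277477,332811,624545,23.07,30.51,57.66,68.67
19,fibrosis,937,616,1175,774,132623,284239,275741,592188,22.98,31.25,47.77,65.11
20,fibrosis,937,616,1175,774,178399,279763,304097,212797,30.91,30.76,52.69,23.40
21,fibrosis,937,616,1175,774,118927,231046,260216,554155,20.60,25.41,45.08,60.93
22,fibrosis,937,616,1175,774,35206,108527,120321,463475,6.10,11.93,20.85,50.96
23,fibrosis,937,616,1175,774,145561,168318,232954,516142,25.22,18.51,40.36,56.75
24,fibrosis,937,616,1175,774,171292,320456,280337,457849,29.68,35.24,48.57,50.34
25,fibrosis,937,616,1175,774,179593,211797,291002,807038,31.11,23.29,50.42,88.74
26,fibrosis,937,616,1175,774,334536,358449,325038,584035,57.96,39.41,56.31,64.22
27,fibrosis,937,616,1175,774,95262,201323,263779,747961,16.50,22.14,45.70,82.24
28,fibrosis,937,616,1175,774,109211,180626,222184,244845,18.92,19.86,38.49,26.92
29,fibrosis,937,616,1175,774,79511,174023,177446,638162,13.78,19.13,30.74,70.17
30,fibrosis,937,616,1175,774,111606,205574,213678,642990,19.34,22.60,37.02,70.70
31,fibrosis,937,616,1175,774,100889,158361,181136,247407,17.48,17.41,31.38,27.20
32,fibrosis,937,616,1175,774,315414,314985,285941,490152,54.65,34.63,49.54,53.90
33,fibrosis,937,616,1175,774,70368,153468,171881,514503,12.19,16.87,29.78,56.57
34,fibrosis,937,616,1175,774,248720,185230,215320,562219,43.09,20.37,37.30,61.82
35,fibrosis,937,616,1175,774,162835,174455,217815,471774,28.21,19.18,37.74,51.87
36,fibrosis,937,616,1175,774,139449,273355,224637,460182,24.16,30.06,38.92,50.60
37,fibrosis,937,616,1175,774,113001,206461,218245,359327,19.58,22.70,37.81,39.51
38,fibrosis,937,616,1175,774,57819,148589,167735,407001,10.02,16.34,29.06,44.75
39,fibrosis,937,616,1175,774,182551,231942,271317,358105,31.63,25.50,47.01,39.38
40,fibrosis,937,616,1175,774,167528,178021,194018,396547,29.02,19.57,33.61,43.60
41,special,937,616,1175,774,0,176801,158203,407651,0,19.44,27.41,44.82
42,special,937,616,1175,774,0,186446,109634,393731,0,20.50,18.99,43.29
43,special,937,616,1175,774,0,16737,40011,663970,0,1.84,6.93,73.01
44,special,937,616,1175,774,0,107014,365001,661809,0,11.77,63.24,72.77
45,special,937,616,1175,774,0,401827,389076,370744,0,44.18,67.41,40.77
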