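sample_id,tissue,material,depth,balance,count_g,frequency_pct
102,thyroid,gDNA,29548,0.49,15054,50.95
102,thyroid,cDNA,9305,0.49,4926,52.94
218,thyroid,gDNA,25800,0.49,13283,51.48
218,thyroid,cDNA,5006,0.49,2746,54.85
355,thyroid,gDNA,15027,0.49,7771,51.71
355,thyroid,cDNA,9200,0.50,4940,53.70
381,thyroid,gDNA,25044,0.49,12633,50.44
381,thyroid,cDNA,23579,0.49,12361,52.42
409,thyroid,gDNA,25049,0.50,12726,50.80
409,thyroid,cDNA,14221,0.49,7211,50.71
430,thyroid,gDNA,29863,0.49,15038,50.36
430,thyroid,cDNA,1693,0.49,764,45.13
452,thyroid,gDNA,32564,0.49,16484,50.62
452,thyroid,cDNA,1738,0.50,877,50.46
92,thyroid,gDNA,20911,0.49,10717,51.25
92,thyroid,cDNA,13439,0.49,6916,51.46
101,thymus,gDNA,28664,0.49,14453,50.42
101,thymus,cDNA,6933,0.49,3960,57.12
117,thymus,gDNA,35762,0.49,18282,51.12
117,thymus,cDNA,5912,0.49,3764,63.67
119,thymus,gDNA,24245,0.49,12165,50.18
119,thymus,cDNA,4570,0.49,2663,58.27
126,thymus,gDNA,28552,0.50,14280,50.01
126,thymus,cDNA,4510,0.49,2481,55.01
145,thymus,gDNA,33290,0.50,16932,50.86
145,thymus,cDNA,17575,0.49,9996,56.88
159,thymus,gDNA,25178,0.50,12664,50.30
159,thymus,cDNA,6616,0.49,4299,64.98
16,thymus,gDNA,22447,0.49,11221,49.99
16,thymus,cDNA,13429,0.49,8649,64.41
171,thymus,gDNA,30800,0.49,15640,50.78
171,thymus,cDNA,4138,0.49,2438,58.92
188,thymus,gDNA,29066,0.49,14720,50.64
188,thymus,cDNA,342,0.48,185,54.09
195,thymus,gDNA,31457,0.49,16255,51.67
195,thymus,cDNA,3656,0.50,2235,61.13
197,thymus,gDNA,31543,0.49,16169,51.26
197,thymus,cDNA,8058,0.49,4385,54.42
225,thymus,gDNA,26017,0.49,13152,50.55
225,thymus,cDNA,18406,0.49,11164,60.65
229,thymus,gDNA,31049,0.50,15955,51.39
229,thymus,cDNA,7373,0.50,4392,59.57
235,thymus,gDNA,31949,0.49,16325,51.10
235,thymus,cDNA,14662,0.49,8516,58.08
263,thymus,gDNA,33124,0.49,16852,50.88
263,thymus,cDNA,16402,0.49,9478,57.79
28,thymus,gDNA,27355,0.49,13931,50.93
28,thymus,cDNA,6143,0.49,3593,58.49
38,thymus,gDNA,4047,0.49,2110,52.14
38,thymus,cDNA,6701,0.50,4253,63.47
4,thymus,gDNA,25273,0.49,12879,50.96
4,thymus,cDNA,16769,0.49,9802,58.45
72,thymus,gDNA,31112,0.49,15957,51.29
72,thymus,cDNA,7426,0.49,4277,57.59
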