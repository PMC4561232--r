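dose,time,variable,value
0,30,dehydrogenases,5.31
0.075,30,dehydrogenases,5.412
2.25,30,dehydrogenases,5.386
11.25,30,dehydrogenases,5.211
22.5,30,dehydrogenases,5.087
0,60,dehydrogenases,9.151
0.075,60,dehydrogenases,9.529
2.25,60,dehydrogenases,9.676
11.25,60,dehydrogenases,9.525
22.5,60,dehydrogenases,8.808
0,90,dehydrogenases,7.255
0.075,90,dehydrogenases,6.645
2.25,90,dehydrogenases,6.621
11.25,90,dehydrogenases,6.489
22.5,90,dehydrogenases,6.309
0,30,catalase,0.36
0.075,30,catalase,0.335
2.25,30,catalase,0.329
11.25,30,catalase,0.299
22.5,30,catalase,0.275
0,60,catalase,0.346
0.075,60,catalase,0.331
2.25,60,catalase,0.302
11.25,60,catalase,0.29
22.5,60,catalase,0.272
0,90,catalase,0.334
0.075,90,catalase,0.331
2.25,90,catalase,0.321
11.25,90,catalase,0.272
22.5,90,catalase,0.262
0,30,urease,0.175
0.075,30,urease,0.164
2.25,30,urease,0.148
11.25,30,urease,0.137
22.5,30,urease,0.131
0,60,urease,0.165
0.075,60,urease,0.165
2.25,60,urease,0.134
11.25,60,urease,0.13
22.5,60,urease,0.11
0,90,urease,0.136
0.075,90,urease,0.132
2.25,90,urease,0.129
11.25,90,urease,0.109
22.5,90,urease,0.092
0,30,acid_phosphatase,0.91
0.075,30,acid_phosphatase,0.902
2.25,30,acid_phosphatase,0.869
11.25,30,acid_phosphatase,0.76
22.5,30,acid_phosphatase,0.705
0,60,acid_phosphatase,0.878
0.075,60,acid_phosphatase,0.837
2.25,60,acid_phosphatase,0.79
11.25,60,acid_phosphatase,0.74
22.5,60,acid_phosphatase,0.694
0,90,acid_phosphatase,0.863
0.075,90,acid_phosphatase,0.828
2.25,90,acid_phosphatase,0.774
11.25,90,acid_phosphatase,0.716
22.5,90,acid_phosphatase,0.686
0,30,alkaline_phosphatase,1.276
0.075,30,alkaline_phosphatase,1.091
2.25,30,alkaline_phosphatase,1.064
11.25,30,alkaline_phosphatase,1.055
22.5,30,alkaline_phosphatase,1.043
0,60,alkaline_phosphatase,2.259
0.075,60,alkaline_phosphatase,2.282
2.25,60,alkaline_phosphatase,2.229
11.25,60,alkaline_phosphatase,2.13
22.5,60,alkaline_phosphatase,2.09
0,90,alkaline_phosphatase,0.47
0.075,90,alkaline_phosphatase,0.496
2.25,90,alkaline_phosphatase,0.49
11.25,90,alkaline_phosphatase,0.431
22.5,90,alkaline_phosphatase,0.406
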