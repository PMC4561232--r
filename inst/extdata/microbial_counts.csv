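dose,time,variable,value
0,30,organotrophic_bacteria,10.186
0.075,30,organotrophic_bacteria,10.294
2.25,30,organotrophic_bacteria,10.315
11.25,30,organotrophic_bacteria,10.384
22.5,30,organotrophic_bacteria,10.406
0,60,organotrophic_bacteria,10.474
0.075,60,organotrophic_bacteria,10.42
2.25,60,organotrophic_bacteria,10.311
11.25,60,organotrophic_bacteria,10.27
22.5,60,organotrophic_bacteria,10.192
0,90,organotrophic_bacteria,10.459
0.075,90,organotrophic_bacteria,10.425
2.25,90,organotrophic_bacteria,10.428
11.25,90,organotrophic_bacteria,10.395
22.5,90,organotrophic_bacteria,10.282
0,30,actinomycetes,9.938
0.075,30,actinomycetes,10.153
2.25,30,actinomycetes,10.087
11.25,30,actinomycetes,9.992
22.5,30,actinomycetes,9.941
0,60,actinomycetes,10.288
0.075,60,actinomycetes,10.199
2.25,60,actinomycetes,10.19
11.25,60,actinomycetes,10.168
22.5,60,actinomycetes,10.137
0,90,actinomycetes,10.293
0.075,90,actinomycetes,10.232
2.25,90,actinomycetes,10.217
11.25,90,actinomycetes,10.206
22.5,90,actinomycetes,10.175
0,30,fungi,7.153
0.075,30,fungi,7.112
2.25,30,fungi,6.878
11.25,30,fungi,6.894
22.5,30,fungi,6.858
0,60,fungi,7.348
0.075,60,fungi,7.26
2.25,60,fungi,7.128
11.25,60,fungi,7.073
22.5,60,fungi,6.951
0,90,fungi,7.44
0.075,90,fungi,7.285
2.25,90,fungi,7.203
11.25,90,fungi,7.112
22.5,90,fungi,7.014
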