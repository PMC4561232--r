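dose,time,variable,value
0.075,90,dehydrogenases,-0.467
2.25,90,dehydrogenases,-0.467
11.25,90,dehydrogenases,-0.508
22.5,90,dehydrogenases,-0.551
0.075,90,catalase,-0.818
2.25,90,catalase,-0.866
11.25,90,catalase,-0.624
22.5,90,catalase,-0.449
0.075,90,urease,-0.491
2.25,90,urease,-0.468
11.25,90,urease,-0.225
22.5,90,urease,-0.062
0.075,90,acid_phosphatase,-0.786
2.25,90,acid_phosphatase,-0.647
11.25,90,acid_phosphatase,-0.536
22.5,90,acid_phosphatase,-0.485
0.075,90,alkaline_phosphatase,0.235
2.25,90,alkaline_phosphatase,0.243
11.25,90,alkaline_phosphatase,0.33
22.5,90,alkaline_phosphatase,0.374
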