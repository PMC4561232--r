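dose,time,variable,value
0.075,30,dehydrogenases,0.949
2.25,30,dehydrogenases,0.884
11.25,30,dehydrogenases,0.931
22.5,30,dehydrogenases,0.878
0.075,60,dehydrogenases,0.925
2.25,60,dehydrogenases,0.898
11.25,60,dehydrogenases,0.92
22.5,60,dehydrogenases,0.918
0.075,90,dehydrogenases,0.817
2.25,90,dehydrogenases,0.828
11.25,90,dehydrogenases,0.793
22.5,90,dehydrogenases,0.743
0.075,30,catalase,0.863
2.25,30,catalase,0.832
11.25,30,catalase,0.667
22.5,30,catalase,0.529
0.075,60,catalase,0.87
2.25,60,catalase,0.61
11.25,60,catalase,0.682
22.5,60,catalase,0.573
0.075,90,catalase,0.878
2.25,90,catalase,0.917
11.25,90,catalase,0.626
22.5,90,catalase,0.568
0.075,30,urease,0.877
2.25,30,urease,0.69
11.25,30,urease,0.573
22.5,30,urease,0.501
0.075,60,urease,0.908
2.25,60,urease,0.635
11.25,60,urease,0.567
22.5,60,urease,0.337
0.075,90,urease,0.803
2.25,90,urease,0.895
11.25,90,urease,0.603
22.5,90,urease,0.366
0.075,30,acid_phosphatase,0.913
2.25,30,acid_phosphatase,0.893
11.25,30,acid_phosphatase,0.675
22.5,30,acid_phosphatase,0.552
0.075,60,acid_phosphatase,0.893
2.25,60,acid_phosphatase,0.802
11.25,60,acid_phosphatase,0.69
22.5,60,acid_phosphatase,0.584
0.075,90,acid_phosphatase,0.901
2.25,90,acid_phosphatase,0.799
11.25,90,acid_phosphatase,0.663
22.5,90,acid_phosphatase,0.592
0.075,30,alkaline_phosphatase,0.711
2.25,30,alkaline_phosphatase,0.667
11.25,30,alkaline_phosphatase,0.654
22.5,30,alkaline_phosphatase,0.633
0.075,60,alkaline_phosphatase,0.964
2.25,60,alkaline_phosphatase,0.968
11.25,60,alkaline_phosphatase,0.886
22.5,60,alkaline_phosphatase,0.851
0.075,90,alkaline_phosphatase,0.905
2.25,90,alkaline_phosphatase,0.922
11.25,90,alkaline_phosphatase,0.836
22.5,90,alkaline_phosphatase,0.727
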