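variable,time,statistic,value,starred
dehydrogenases,30,mean,5.281,NA
dehydrogenases,60,mean,9.338,NA
dehydrogenases,90,mean,6.664,NA
catalase,30,mean,0.32,NA
catalase,60,mean,0.308,NA
catalase,90,mean,0.304,NA
urease,30,mean,0.151,NA
urease,60,mean,0.141,NA
urease,90,mean,0.119,NA
acid_phosphatase,30,mean,0.829,NA
acid_phosphatase,60,mean,0.788,NA
acid_phosphatase,90,mean,0.773,NA
alkaline_phosphatase,30,mean,1.106,NA
alkaline_phosphatase,60,mean,2.198,NA
alkaline_phosphatase,90,mean,0.458,NA
dehydrogenases,30,r,-0.945,TRUE
dehydrogenases,60,r,-0.652,FALSE
dehydrogenases,90,r,-0.727,FALSE
catalase,30,r,-0.946,TRUE
catalase,60,r,-0.884,TRUE
catalase,90,r,-0.952,TRUE
urease,30,r,-0.86,FALSE
urease,60,r,-0.892,TRUE
urease,90,r,-0.993,TRUE
acid_phosphatase,30,r,-0.978,TRUE
acid_phosphatase,60,r,-0.925,TRUE
acid_phosphatase,90,r,-0.908,TRUE
alkaline_phosphatase,30,r,-0.555,FALSE
alkaline_phosphatase,60,r,-0.961,TRUE
alkaline_phosphatase,90,r,-0.942,TRUE
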