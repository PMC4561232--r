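variable,time,statistic,value,starred
dehydrogenases,30,mean,0.911,NA
dehydrogenases,60,mean,0.915,NA
dehydrogenases,90,mean,0.795,NA
catalase,30,mean,0.723,NA
catalase,60,mean,0.684,NA
catalase,90,mean,0.747,NA
urease,30,mean,0.66,NA
urease,60,mean,0.612,NA
urease,90,mean,0.667,NA
acid_phosphatase,30,mean,0.758,NA
acid_phosphatase,60,mean,0.742,NA
acid_phosphatase,90,mean,0.739,NA
alkaline_phosphatase,30,mean,0.666,NA
alkaline_phosphatase,60,mean,0.917,NA
alkaline_phosphatase,90,mean,0.847,NA
dehydrogenases,30,r,-0.519,FALSE
dehydrogenases,60,r,0.21,FALSE
dehydrogenases,90,r,-0.972,TRUE
catalase,30,r,-0.997,TRUE
catalase,60,r,-0.656,FALSE
catalase,90,r,-0.933,TRUE
urease,30,r,-0.933,TRUE
urease,60,r,-0.918,TRUE
urease,90,r,-0.969,TRUE
acid_phosphatase,30,r,-0.986,TRUE
acid_phosphatase,60,r,-0.975,TRUE
acid_phosphatase,90,r,-0.951,TRUE
alkaline_phosphatase,30,r,-0.874,FALSE
alkaline_phosphatase,60,r,-0.972,TRUE
alkaline_phosphatase,90,r,-0.984,TRUE
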