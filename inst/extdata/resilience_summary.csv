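variable,time,statistic,value,starred
dehydrogenases,90,mean,-0.498,NA
catalase,90,mean,-0.689,NA
urease,90,mean,-0.312,NA
acid_phosphatase,90,mean,-0.614,NA
alkaline_phosphatase,90,mean,0.296,NA
dehydrogenases,90,r,-0.996,TRUE
catalase,90,r,0.979,TRUE
urease,90,r,0.991,TRUE
acid_phosphatase,90,r,0.902,FALSE
alkaline_phosphatase,90,r,0.982,TRUE
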