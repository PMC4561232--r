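variable,time,statistic,value,starred
organotrophic_bacteria,30,mean,10.32,NA
organotrophic_bacteria,60,mean,10.34,NA
organotrophic_bacteria,90,mean,10.4,NA
actinomycetes,30,mean,10.02,NA
actinomycetes,60,mean,10.2,NA
actinomycetes,90,mean,10.23,NA
fungi,30,mean,7,NA
fungi,60,mean,7.17,NA
fungi,90,mean,7.22,NA
organotrophic_bacteria,30,r,0.813,FALSE
organotrophic_bacteria,60,r,-0.891,TRUE
organotrophic_bacteria,90,r,-0.963,TRUE
actinomycetes,30,r,-0.547,FALSE
actinomycetes,60,r,-0.762,FALSE
actinomycetes,90,r,-0.791,FALSE
fungi,30,r,-0.709,FALSE
fungi,60,r,-0.902,TRUE
fungi,90,r,-0.876,TRUE
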