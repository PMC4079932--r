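sex,age,ex,lo,hi
men,60,19.2,18.2,20.2
men,65,15.6,14.6,16.5
men,70,12.4,11.5,13.2
men,75,9.4,8.7,10.2
men,80,7.3,NA,NA
women,60,23.7,22.8,24.6
women,65,19.6,18.8,20.5
women,70,15.7,15.0,16.5
women,75,12.3,11.7,12.9
women,80,9.3,NA,NA
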